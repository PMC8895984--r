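# Synthetic inbred founders: fully homozygous 0/1 genotypes at the map's
# markers, with optional planted tracts of pairwise identity-by-descent.

#' Construct a founder set
#'
#' @param geno founders x markers matrix of 0/1 alleles, with rownames
#'   (founder ids) and colnames matching the map's marker names.
#' @param map a `genetic_map`
#' @param ibd_truth optional data.frame of planted IBD tracts
#'   (`founder1`, `founder2`, `chrom`, `start_bp`, `end_bp`,
#'   `start_cm`, `end_cm`)
#' @return object of class `founder_set`
#' @export
founder_set <- function(geno, map, ibd_truth = NULL) {
  if (!all(colnames(geno) == map$marker))
    stop_invalid("founder genotype columns must match the map's markers")
  vals <- geno[!is.na(geno)]
  if (!all(vals %in% c(0, 1)))
    stop_invalid("founder alleles must be 0/1 (inbred, homozygous)")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("F", seq_len(nrow(geno)))
  structure(list(geno = geno, map = map, ibd_truth = ibd_truth),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat("Founder set:", nrow(x$geno), "founders x", ncol(x$geno), "markers\n")
  if (!is.null(x$ibd_truth))
    cat("  planted IBD tracts:", nrow(x$ibd_truth), "\n")
  invisible(x)
}

#' Number and ids of founders
#' @param founders a `founder_set`
#' @export
n_founders <- function(founders) nrow(founders$geno)

#' @rdname n_founders
#' @export
founder_ids <- function(founders) rownames(founders$geno)

#' Simulate a set of inbred founders
#'
#' Alleles are drawn independently per founder and marker with a
#' marker-frequency chosen so that two founders differ at an expected
#' fraction `divergence` of markers. Optional planted IBD tracts
#' (`ibd_plan`) force groups of founders to share alleles over a cM window;
#' overlapping tracts are resolved transitively (all founders connected
#' through tracts at a marker receive the allele of the lowest-indexed
#' member), so the plan can never be self-contradictory. The planted tracts
#' are recorded as IBD truth for downstream recovery checks.
#'
#' With more than two founders the expected pairwise difference of
#' exchangeable bi-allelic genotypes cannot exceed 1/2, so `divergence`
#' is limited to (0, 0.5] unless `f = 2`.
#'
#' @param map a `genetic_map`
#' @param f number of founders (>= 2; default 16)
#' @param divergence expected fraction of markers at which a founder pair
#'   differs (default 0.5, emulating array-ascertained common variants)
#' @param ibd_plan optional data.frame with columns `founder1`, `founder2`
#'   (ids or indices), `chrom`, `start_cm`, `end_cm`
#' @param seed optional RNG seed
#' @return a `founder_set`
#' @examples
#' map <- simulate_map(1, 200, 100, 1e6, seed = 1)
#' fnd <- simulate_founders(map, f = 16, divergence = 0.3, seed = 2)
#' @export
simulate_founders <- function(map, f = 16, divergence = 0.5,
                              ibd_plan = NULL, seed = NULL) {
  set_seed_if(seed)
  if (f < 2) stop_invalid("need at least 2 founders")
  if (divergence <= 0 || divergence > 1)
    stop_invalid("divergence must be in (0, 1]")
  m <- nrow(map)
  ids <- paste0("F", seq_len(f))
  if (f == 2L) {
    g1 <- rbinom(m, 1, 0.5)
    g2 <- (g1 + rbinom(m, 1, divergence)) %% 2
    geno <- rbind(g1, g2)
  } else {
    if (divergence > 0.5)
      stop_invalid("divergence > 0.5 is unattainable for more than 2 founders")
    q <- (1 - sqrt(1 - 2 * divergence)) / 2
    geno <- matrix(rbinom(f * m, 1, q), nrow = f)
  }
  dimnames(geno) <- list(ids, map$marker)

  truth <- NULL
  if (!is.null(ibd_plan) && nrow(ibd_plan) > 0) {
    plan <- .normalize_ibd_plan(ibd_plan, ids, map)
    geno <- .apply_ibd_plan(geno, plan, map)
    truth <- plan
  }
  founder_set(geno, map, ibd_truth = truth)
}

.normalize_ibd_plan <- function(plan, ids, map) {
  need <- c("founder1", "founder2", "chrom", "start_cm", "end_cm")
  if (!all(need %in% names(plan)))
    stop_invalid("invalid-plan: ibd_plan needs columns ",
                 paste(need, collapse = ", "))
  f1 <- .founder_index(plan$founder1, ids)
  f2 <- .founder_index(plan$founder2, ids)
  if (any(f1 == f2)) stop_invalid("invalid-plan: tract pairs a founder with itself")
  swap <- f1 > f2
  tmp <- f1[swap]; f1[swap] <- f2[swap]; f2[swap] <- tmp
  if (any(plan$end_cm <= plan$start_cm))
    stop_invalid("invalid-plan: tract end_cm must exceed start_cm")
  if (!all(plan$chrom %in% map_chromosomes(map)))
    stop_invalid("invalid-plan: unknown chromosome in ibd_plan")
  out <- data.frame(founder1 = ids[f1], founder2 = ids[f2],
                    chrom = as.character(plan$chrom),
                    start_cm = plan$start_cm, end_cm = plan$end_cm,
                    stringsAsFactors = FALSE)
  out$start_bp <- NA_real_
  out$end_bp <- NA_real_
  for (i in seq_len(nrow(out))) {
    out$start_bp[i] <- cm_to_bp(map, out$chrom[i], out$start_cm[i])
    out$end_bp[i] <- cm_to_bp(map, out$chrom[i], out$end_cm[i])
  }
  out
}

.founder_index <- function(x, ids) {
  if (is.numeric(x)) {
    if (any(x < 1 | x > length(ids))) stop_invalid("invalid-plan: founder index out of range")
    return(as.integer(x))
  }
  idx <- match(as.character(x), ids)
  if (anyNA(idx)) stop_invalid("invalid-plan: unknown founder id")
  idx
}

# per marker, union founders connected through covering tracts and copy the
# allele of the lowest-indexed member to the whole group
.apply_ibd_plan <- function(geno, plan, map) {
  f <- nrow(geno)
  ids <- rownames(geno)
  for (cc in unique(plan$chrom)) {
    mcols <- which(map$chrom == cc)
    cm <- map$cm[mcols]
    tr <- plan[plan$chrom == cc, , drop = FALSE]
    covered <- lapply(seq_len(nrow(tr)), function(i)
      mcols[cm >= tr$start_cm[i] & cm <= tr$end_cm[i]])
    touched <- sort(unique(unlist(covered)))
    for (j in touched) {
      active <- which(vapply(covered, function(z) j %in% z, logical(1)))
      parent <- seq_len(f)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in active) {
        a <- find(match(tr$founder1[k], ids)); b <- find(match(tr$founder2[k], ids))
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_len(f), find, integer(1))
      geno[, j] <- geno[cbind(roots, j)]
    }
  }
  geno
}
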