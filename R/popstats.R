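# Population-level diagnostics: founder-representation chi-squared tests
# with a simulation-derived genome-wide threshold, linkage-disequilibrium
# structure (intra- and interchromosomal), permutation gene-set
# enrichment, and epistasis scans around a focal locus.

#' Test for equal representation of founders at each site
#'
#' At each marker, the number of lines with posterior probability greater
#' than `prob_threshold` for a founder approximates the number of lines
#' carrying that founder; the counts are tested against the equal-share
#' expectation n/f with a chi-squared statistic (df = f - 1). The
#' genome-wide 5% threshold is taken from simulated null populations:
#' by default the 5th percentile of each null population's minimum
#' per-site p-value (a family-wise min-p rule); alternatively
#' (`null_rule = "pooled"`) the 5th percentile of the pooled per-site
#' p-values of all null populations.
#'
#' @param posterior a `founder_posterior` for the observed population
#' @param prob_threshold confident-carrier probability (default 0.8)
#' @param null_posteriors optional list of `founder_posterior` objects
#'   from simulated null populations of the same design
#' @param alpha genome-wide error rate for the threshold (default 0.05)
#' @param null_rule `"minp"` (default) or `"pooled"`
#' @return list with `sites` (per-marker counts, chisq, p, tested flag),
#'   `threshold_p` (NULL without null populations), `significant_fraction`
#' @export
founder_representation_test <- function(posterior, prob_threshold = 0.8,
                                        null_posteriors = NULL,
                                        alpha = 0.05,
                                        null_rule = c("minp", "pooled")) {
  null_rule <- match.arg(null_rule)
  tab <- .representation_chisq(posterior, prob_threshold)
  threshold_p <- NULL
  if (!is.null(null_posteriors) && length(null_posteriors)) {
    null_p <- lapply(null_posteriors, function(pp)
      .representation_chisq(pp, prob_threshold)$p)
    threshold_p <- if (null_rule == "minp") {
      unname(quantile(vapply(null_p, min, 1, na.rm = TRUE), alpha, type = 7))
    } else {
      unname(quantile(unlist(null_p), alpha, na.rm = TRUE, type = 7))
    }
  }
  sig <- if (is.null(threshold_p)) NA
         else mean(tab$p < threshold_p, na.rm = TRUE)
  list(sites = tab, threshold_p = threshold_p, significant_fraction = sig)
}

.representation_chisq <- function(posterior, prob_threshold) {
  map <- attr(posterior, "map")
  n <- dim(posterior)[1]; M <- dim(posterior)[2]; f <- dim(posterior)[3]
  counts <- matrix(0L, M, f)
  for (k in seq_len(f))
    counts[, k] <- colSums(matrix(posterior[, , k] > prob_threshold, n))
  expected <- n / f
  chisq <- rowSums((counts - expected)^2 / expected)
  tested <- rowSums(counts) > 0L
  p <- ifelse(tested, pchisq(chisq, df = f - 1, lower.tail = FALSE), NA)
  data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
             n_counted = rowSums(counts), chisq = ifelse(tested, chisq, NA),
             p = p, tested = tested, stringsAsFactors = FALSE)
}

#' Pairwise linkage disequilibrium and high interchromosomal LD regions
#'
#' R^2 is the squared Pearson correlation of allele counts. All pairs are
#' classified as intra- or interchromosomal; interchromosomal pairs with
#' R^2 above `r2_cutoff` are counted, and runs of consecutive SNPs on one
#' chromosome each having a high-LD partner on another chromosome are
#' reported as regions with a size class (>5 Mb, 1-5 Mb, 100 kb-1 Mb,
#' <100 kb).
#'
#' @param geno lines x markers 0/1 matrix
#' @param map a `genetic_map` matching the columns
#' @param r2_cutoff high-LD cutoff (default 0.9)
#' @param max_pairs optional cap: at most this many randomly sampled pairs
#'   are used for the R^2 summary (counts of high-LD pairs always use all
#'   pairs)
#' @param seed RNG seed used when sampling pairs
#' @return list with `n_intra`, `n_inter` (pair counts), `n_intra_high`,
#'   `n_inter_high` (pairs with R^2 >= cutoff), `high_fraction_inter`,
#'   `regions` (consecutive-SNP high-LD regions), `r2_sample` (optional
#'   sampled pair table)
#' @export
ld_r2 <- function(geno, map, r2_cutoff = 0.9, max_pairs = NULL, seed = NULL) {
  set_seed_if(seed)
  s <- apply(geno, 2, sd)
  use <- s > 0
  g <- geno[, use, drop = FALSE]
  chrom <- map$chrom[use]
  bp <- map$bp[use]
  M <- ncol(g)
  R2 <- suppressWarnings(cor(g))^2
  inter <- outer(chrom, chrom, `!=`)
  ut <- upper.tri(R2)
  n_inter <- sum(inter & ut)
  n_intra <- sum(ut) - n_inter
  high <- R2 >= r2_cutoff & ut
  n_inter_high <- sum(high & inter, na.rm = TRUE)
  n_intra_high <- sum(high & !inter, na.rm = TRUE)

  # consecutive-SNP regions with an interchromosomal high-LD partner
  partner <- (R2 >= r2_cutoff) & inter
  has_partner <- rowSums(partner, na.rm = TRUE) > 0
  regions <- list()
  for (cc in unique(chrom)) {
    ii <- which(chrom == cc)
    r <- rle(has_partner[ii])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      a <- ii[starts[k]]; b <- ii[ends[k]]
      size <- bp[b] - bp[a]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = cc, start_bp = bp[a], end_bp = bp[b], n_snps = ends[k] - starts[k] + 1L,
        size_class = if (size > 5e6) ">5Mb" else if (size >= 1e6) "1-5Mb"
                     else if (size >= 1e5) "100kb-1Mb" else "<100kb",
        stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions)
             else data.frame(chrom = character(0), start_bp = numeric(0),
                             end_bp = numeric(0), n_snps = integer(0),
                             size_class = character(0))
  r2_sample <- NULL
  if (!is.null(max_pairs)) {
    pick <- cbind(sample.int(M, max_pairs, replace = TRUE),
                  sample.int(M, max_pairs, replace = TRUE))
    pick <- pick[pick[, 1] != pick[, 2], , drop = FALSE]
    r2_sample <- data.frame(r2 = R2[pick],
                            inter = inter[pick])
  }
  list(n_intra = n_intra, n_inter = n_inter,
       n_intra_high = n_intra_high, n_inter_high = n_inter_high,
       high_fraction_inter = if (n_inter_high + n_intra_high > 0)
         n_inter_high / (n_inter_high + n_intra_high) else 0,
       regions = regions, r2_sample = r2_sample)
}

# does each interval in `q` overlap (>= 1 bp) any interval in `r`?
.overlaps_any <- function(q, r) {
  out <- logical(nrow(q))
  for (cc in unique(q$chrom)) {
    qi <- which(q$chrom == cc)
    ri <- which(r$chrom == cc)
    if (!length(ri)) next
    rs <- r$start[ri]; re <- r$end[ri]
    o <- order(rs); rs <- rs[o]; re <- cummax(re[o])
    pos <- findInterval(q$end[qi] - 1e-9, rs)
    hit <- pos >= 1 & q$start[qi] < re[pmax(pos, 1)]
    out[qi] <- ifelse(pos >= 1, hit, FALSE)
  }
  out
}

#' Permutation enrichment of a gene set in genomic regions
#'
#' Counts focal genes overlapping the regions (>= 1 bp), then draws
#' `n_perm` random same-size samples from the background genes and counts
#' their overlaps; p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param regions data.frame with `chrom`, `start`, `end`
#' @param focal_genes,background_genes data.frames with `chrom`, `start`,
#'   `end` (background must be at least as large as the focal set)
#' @param n_perm number of permutations (default 1000)
#' @param seed optional RNG seed
#' @return list with `observed`, `null` (vector of permuted counts), `p`
#' @export
enrichment_test <- function(regions, focal_genes, background_genes,
                            n_perm = 1000, seed = NULL) {
  set_seed_if(seed)
  nf <- nrow(focal_genes)
  if (nrow(background_genes) < nf)
    stop_invalid("background gene set smaller than the focal set")
  obs <- sum(.overlaps_any(focal_genes, regions))
  bg_hit <- .overlaps_any(background_genes, regions)
  null <- vapply(seq_len(n_perm), function(i)
    sum(bg_hit[sample.int(length(bg_hit), nf)]), 1L)
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Probability that each line carries a focal allele
#'
#' Sums the founder posterior probabilities of the carrier founders at the
#' tested marker closest to the focal site. Lines with probability
#' strictly between `lower` and `upper` have an uncertain allelic state
#' and are flagged for dropping.
#'
#' @param posterior a `founder_posterior`
#' @param chrom,bp focal site (mapped to the nearest marker)
#' @param carrier_founders founder ids or indices carrying the allele
#' @param lower,upper uncertainty band (defaults 0.05 and 0.95)
#' @return data.frame with `line`, `prob`, `carrier` (prob >= upper),
#'   `uncertain`
#' @export
focal_allele_probability <- function(posterior, chrom, bp, carrier_founders,
                                     lower = 0.05, upper = 0.95) {
  if (!length(carrier_founders)) stop_invalid("empty carrier founder set")
  map <- attr(posterior, "map")
  ids <- dimnames(posterior)[[3]]
  ci <- if (is.numeric(carrier_founders)) as.integer(carrier_founders)
        else match(carrier_founders, ids)
  if (anyNA(ci) || any(ci < 1 | ci > length(ids)))
    stop_invalid("unknown carrier founder")
  mi <- which(map$chrom == as.character(chrom))
  if (!length(mi)) stop_invalid("no markers on chromosome ", chrom)
  j <- mi[which.min(abs(map$bp[mi] - bp))]
  n <- dim(posterior)[1]
  pm <- matrix(posterior[, j, ], n, dim(posterior)[3])
  prob <- rowSums(pm[, ci, drop = FALSE])
  data.frame(line = dimnames(posterior)[[1]], prob = prob,
             carrier = prob >= upper,
             uncertain = prob > lower & prob < upper,
             stringsAsFactors = FALSE)
}

#' Genome scan for epistasis with a focal locus
#'
#' Per SNP, fits the mixed model with main effects of carrier status and
#' SNP dosage plus their interaction, and tests the interaction by
#' likelihood ratio (df = 1). Lines with uncertain carrier status must be
#' dropped beforehand. Significance uses a Bonferroni threshold of
#' `alpha / n_tests`.
#'
#' @param y response per line (uncertain lines removed)
#' @param carrier binary carrier status per line
#' @param geno lines x markers SNP matrix (same lines)
#' @param map a `genetic_map` matching the columns
#' @param K_loco per-chromosome kinship list (or single matrix / NULL)
#' @param alpha family-wise error rate for the Bonferroni flag
#'   (default 0.05)
#' @param grid_step h2 grid resolution (default 0.01)
#' @return data.frame per tested SNP: marker, chrom, bp, p_interaction,
#'   significant (Bonferroni), skipped
#' @export
epistasis_scan <- function(y, carrier, geno, map, K_loco = NULL,
                           alpha = 0.05, grid_step = 0.01) {
  carrier <- as.numeric(carrier)
  if (!all(carrier %in% c(0, 1))) stop_invalid("carrier status must be binary")
  n <- length(y)
  M <- nrow(map)
  p_int <- rep(NA_real_, M)
  skipped <- logical(M)
  for (cc in map_chromosomes(map)) {
    jj <- which(map$chrom == cc)
    K <- if (is.null(K_loco)) NULL
         else if (is.list(K_loco)) K_loco[[cc]] else K_loco
    Xlist <- vector("list", length(jj))
    ok <- logical(length(jj))
    for (t in seq_along(jj)) {
      snp <- geno[, jj[t]]
      inter <- carrier * snp
      # interaction must not be collinear with the main effects
      mm <- cbind(1, carrier, snp, inter)
      if (sd(snp) == 0 || qr(mm)$rank < 4L) { skipped[jj[t]] <- TRUE; next }
      Xlist[[t]] <- cbind(snp = snp, inter = inter)
      ok[t] <- TRUE
    }
    if (!any(ok)) next
    # null design includes carrier and SNP main effects; the marker term
    # is the interaction column. SNP main effect differs per marker, so
    # fit marker-wise with covariates = carrier + snp via the two-column
    # trick: alt design = (snp, inter), null refit = (snp) handled by
    # comparing against the snp-only model.
    X0 <- cbind(`(Intercept)` = rep(1, n), carrier = carrier)
    grid <- .h2_grid(grid_step)
    alt <- .scan_chrom(matrix(y), X0, Xlist[ok], K, grid)
    nul <- .scan_chrom(matrix(y), X0,
                       lapply(Xlist[ok], function(m) m[, "snp", drop = FALSE]),
                       K, grid)
    lrt <- 2 * (alt$ll_alt[, 1] - nul$ll_alt[, 1])
    lrt[lrt < 0] <- 0
    pj <- pchisq(lrt, df = 1, lower.tail = FALSE)
    pj[!alt$ok | !nul$ok] <- NA
    p_int[jj[ok]] <- pj
  }
  tested <- !is.na(p_int)
  thr <- alpha / max(sum(tested), 1L)
  data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
             p_interaction = p_int,
             significant = tested & p_int < thr,
             skipped = skipped, stringsAsFactors = FALSE)
}

#' QTL scan restricted to a background subset of lines
#'
#' Runs [genome_scan()] using only the masked lines (e.g. confident
#' carriers of a focal allele), with the kinship matrices subset to those
#' lines; the permutation threshold should be recomputed on the subset
#' with [permutation_threshold()].
#'
#' @inheritParams genome_scan
#' @param mask logical or integer index of lines to keep
#' @return a `magic_scan` on the subset
#' @export
background_subset_scan <- function(y, markers, K_loco = NULL, mask,
                                   covariates = NULL, grid_step = 0.01,
                                   test = c("lrt", "f")) {
  test <- match.arg(test)
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  sub <- subset_lines(markers, idx)
  maxp <- max(vapply(sub$X, ncol, 1L)) + 1L + NCOL(covariates %||% matrix(nrow = 0, ncol = 0))
  if (sub$n <= maxp)
    stop_invalid("subset too small for the design (n = ", sub$n, ")")
  Ksub <- if (is.null(K_loco)) NULL
          else if (is.list(K_loco)) lapply(K_loco, function(K) K[idx, idx])
          else K_loco[idx, idx]
  genome_scan(y[idx], sub, K_loco = Ksub,
              covariates = if (is.null(covariates)) NULL
                           else covariates[idx, , drop = FALSE],
              grid_step = grid_step, test = test)
}
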