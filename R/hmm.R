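# Hidden Markov model for founder ancestry of doubled haploid lines.
#
# Hidden state at each marker = founder of origin (f states). Emission:
# the observed allele matches the founder's allele with probability
# 1 - error, mismatches with probability error; missing genotypes emit 1
# for every founder (no information). Transition between adjacent markers
# at map distance d cM uses the recombination fraction
#   r = (1 - exp(-2 g d / 100)) / 2,
# where g is an effective map-expansion factor approximating the number of
# recombining meioses accumulated by the crossing scheme (default 7 for a
# funnel + 3 intercross generations + DH induction). Conditional on a
# recombination the new founder is uniform over the other f - 1 founders.
# Forward-backward is run per line and chromosome with per-marker scaling.

#' Infer founder ancestry probabilities along each line's genome
#'
#' @param line_geno lines x markers matrix of 0/1 alleles (NA = missing),
#'   columns matching the map's markers
#' @param founders a `founder_set`
#' @param map a `genetic_map` (defaults to the founders' map)
#' @param error genotyping-error rate in [0, 0.5) (default 0.002)
#' @param gens effective map-expansion factor g > 0 (default 7)
#' @return object of class `founder_posterior`: a lines x markers x
#'   founders array of posterior probabilities with the map attached as an
#'   attribute; every (line, marker) slice sums to 1. Lines with no
#'   genotype at all are flagged in attribute `"all_missing"` and get
#'   uniform posteriors.
#' @examples
#' map <- simulate_map(1, 60, 80, 1e6, seed = 1)
#' fnd <- simulate_founders(map, f = 4, seed = 2)
#' pop <- simulate_magic(fnd, magic_scheme(4, 1, 30, n_dh = 8), seed = 3)
#' post <- infer_founder_probabilities(mosaic_to_genotypes(pop, fnd), fnd)
#' @export
infer_founder_probabilities <- function(line_geno, founders, map = NULL,
                                        error = 0.002, gens = 7) {
  map <- map %||% founders$map
  if (error < 0 || error >= 0.5) stop_invalid("error must be in [0, 0.5)")
  if (gens <= 0) stop_invalid("gens must be > 0")
  if (is.null(dim(line_geno))) line_geno <- matrix(line_geno, nrow = 1)
  if (ncol(line_geno) != nrow(map) ||
      (!is.null(colnames(line_geno)) && !all(colnames(line_geno) == map$marker)))
    stop_invalid("line genotype markers do not match the map")
  n <- nrow(line_geno)
  f <- n_founders(founders)
  M <- nrow(map)
  lines <- rownames(line_geno) %||% sprintf("L%03d", seq_len(n))
  post <- array(NA_real_, c(n, M, f),
                dimnames = list(lines, map$marker, founder_ids(founders)))

  for (cc in map_chromosomes(map)) {
    idx <- which(map$chrom == cc)
    m <- length(idx)
    d <- diff(map$cm[idx])
    r <- 0.5 * (1 - exp(-2 * gens * d / 100))
    stay_minus_move <- (1 - r) - r / (f - 1)
    move <- r / (f - 1)
    # emissions: list of n x f matrices
    emis <- vector("list", m)
    fg <- founders$geno[, idx, drop = FALSE]
    for (k in seq_len(m)) {
      obs <- line_geno[, idx[k]]
      e <- matrix(1, n, f)
      ok <- !is.na(obs)
      if (any(ok)) {
        match_mat <- outer(obs[ok], fg[, k], `==`)
        e[ok, ] <- ifelse(match_mat, 1 - error, error)
      }
      emis[[k]] <- e
    }
    # renormalize rows; a row of all-zero likelihood (possible only with
    # error = 0 and data discordant with every founder) falls back to
    # uniform rather than propagating NaN
    renorm <- function(x) {
      s <- rowSums(x)
      bad <- s == 0
      if (any(bad)) { x[bad, ] <- 1; s[bad] <- f }
      x / s
    }
    # scaled forward
    alpha <- vector("list", m)
    a <- renorm(emis[[1]] / f)
    alpha[[1]] <- a
    for (k in seq_len(m - 1L)) {
      a <- (stay_minus_move[k] * a + move[k] * rowSums(a)) * emis[[k + 1L]]
      a <- renorm(a)
      alpha[[k + 1L]] <- a
    }
    # scaled backward, combined on the fly
    b <- matrix(1, n, f)
    post[, idx[m], ] <- alpha[[m]]
    for (k in rev(seq_len(m - 1L))) {
      eb <- emis[[k + 1L]] * b
      b <- renorm(stay_minus_move[k] * eb + move[k] * rowSums(eb))
      post[, idx[k], ] <- renorm(alpha[[k]] * b)
    }
  }
  all_missing <- rowSums(!is.na(line_geno)) == 0L
  if (any(all_missing))
    warning(sum(all_missing), " line(s) with no genotypes; posterior uniform")
  structure(post, map = map, error = error, gens = gens,
            all_missing = lines[all_missing],
            class = c("founder_posterior", "array"))
}

#' Maximum-a-posteriori founder path
#'
#' Per-marker argmax founder for each line; ties broken toward the lowest
#' founder index.
#' @param posterior a `founder_posterior`
#' @return lines x markers integer matrix
#' @export
map_founder_path <- function(posterior) {
  n <- dim(posterior)[1]; M <- dim(posterior)[2]; f <- dim(posterior)[3]
  out <- matrix(NA_integer_, n, M,
                dimnames = dimnames(posterior)[1:2])
  for (j in seq_len(M))
    out[, j] <- max.col(matrix(posterior[, j, ], n, f), ties.method = "first")
  out
}

#' Founder assignment accuracy against simulation truth
#'
#' @param posterior a `founder_posterior`
#' @param pop the `magic_population` the genotypes came from (the truth)
#' @param confidence probability above which a call counts as confident
#'   (default 0.8)
#' @return list with `accuracy` (fraction of (line, marker) cells whose
#'   argmax founder equals the true founder) and `confident_fraction`
#'   (cells with maximum posterior probability > `confidence`)
#' @export
assignment_accuracy <- function(posterior, pop, confidence = 0.8) {
  truth <- true_founder_matrix(pop, attr(posterior, "map"))
  pred <- map_founder_path(posterior)
  if (!all(dim(truth) == dim(pred)))
    stop_invalid("truth mosaics do not cover the posterior's markers")
  f <- dim(posterior)[3]
  maxp <- Reduce(pmax, lapply(seq_len(f), function(k) posterior[, , k]))
  list(accuracy = mean(pred == truth),
       confident_fraction = mean(maxp > confidence))
}
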