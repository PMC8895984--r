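# Linear mixed-model machinery: genomic relationship matrices (overall and
# leave-one-chromosome-out), marker-set containers for the three allelic
# models, and the grid-profile ML fit behind all genome scans.
#
# Model:  y = mu + X_i beta_i + Z u + e,  u ~ N(0, sigma2_u K),
# with one record per line (Z = I; multi-environment data enter through
# BLUPs, see calc_blups). Writing h2 = sigma2_u / (sigma2_u + sigma2_e),
# the covariance is sigma2 * (h2 K + (1 - h2) I). After one
# eigendecomposition of K per (chromosome, phenotype) the likelihood is
# profiled over h2 on a fixed grid; each marker is tested against the
# no-marker null refit on the same grid, by likelihood-ratio chi-squared
# (df = number of marker columns) or by the GLS F test at the marker's
# ML-optimal h2 (the F route reduces exactly to the ordinary-least-squares
# F test when sigma2_u = 0).

#' Genomic relationship matrix
#'
#' Columns are centered and scaled; monomorphic markers are skipped; the
#' cross-product is divided by the number of markers used.
#' @param geno lines x markers 0/1 matrix
#' @param map optional `genetic_map` (unused here, kept for symmetry)
#' @return n x n relationship matrix
#' @export
compute_grm <- function(geno, map = NULL) {
  s <- apply(geno, 2, sd)
  use <- which(s > 0)
  if (!length(use)) stop_invalid("all markers are monomorphic")
  X <- scale(geno[, use, drop = FALSE])
  K <- tcrossprod(X) / length(use)
  dimnames(K) <- list(rownames(geno), rownames(geno))
  K
}

#' Leave-one-chromosome-out kinship matrices
#'
#' For each chromosome c, the relationship matrix is built from all
#' markers *not* on c, avoiding proximal contamination of the polygenic
#' term by the tested locus.
#' @param geno lines x markers 0/1 matrix, columns matching the map
#' @param map a `genetic_map` with at least 2 chromosomes
#' @return named list of n x n matrices, one per chromosome
#' @export
compute_grm_loco <- function(geno, map) {
  chroms <- map_chromosomes(map)
  if (length(chroms) < 2L)
    stop_invalid("LOCO kinship needs at least 2 chromosomes")
  out <- lapply(chroms, function(cc)
    compute_grm(geno[, map$chrom != cc, drop = FALSE]))
  names(out) <- chroms
  out
}

## ---- marker sets ----------------------------------------------------------

.new_marker_set <- function(type, model, info, X, n, full = NULL) {
  structure(list(type = type, model = model, info = info, X = X, n = n,
                 full = full),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker set (", x$model, "): ", nrow(x$info), " markers x ",
      x$n, " lines\n", sep = "")
  invisible(x)
}

#' Marker set for the bi-allelic SNP model (GWAS_SNP)
#'
#' @param geno lines x markers 0/1 matrix
#' @param map a `genetic_map` matching the columns
#' @param keep optional marker names to keep
#' @return a `marker_set` whose per-marker design is the n x 1 allele
#'   vector
#' @export
snp_markers <- function(geno, map, keep = NULL) {
  idx <- if (is.null(keep)) seq_len(nrow(map)) else match(keep, map$marker)
  if (anyNA(idx)) stop_invalid("unknown marker in keep")
  X <- lapply(idx, function(j) cbind(snp = geno[, j]))
  info <- data.frame(marker = map$marker[idx], chrom = map$chrom[idx],
                     bp = map$bp[idx], cm = map$cm[idx],
                     stringsAsFactors = FALSE)
  .new_marker_set("snp", "GWAS_SNP", info, X, nrow(geno),
                  full = lapply(idx, function(j)
                    cbind(ref = 1 - geno[, j], alt = geno[, j])))
}

#' Marker set for the founder model (QTL_F)
#'
#' @param posterior a `founder_posterior`
#' @param keep optional marker names (e.g. from
#'   [filter_probability_markers()])
#' @return a `marker_set` whose per-marker design is the n x (f - 1)
#'   founder-probability matrix with the first founder's column dropped as
#'   reference
#' @export
founder_markers <- function(posterior, keep = NULL) {
  map <- attr(posterior, "map")
  idx <- if (is.null(keep)) seq_len(nrow(map)) else match(keep, map$marker)
  if (anyNA(idx)) stop_invalid("unknown marker in keep")
  n <- dim(posterior)[1]; f <- dim(posterior)[3]
  fids <- dimnames(posterior)[[3]]
  full <- lapply(idx, function(j) {
    m <- matrix(posterior[, j, ], n, f)
    colnames(m) <- fids
    m
  })
  X <- lapply(full, function(m) m[, -1L, drop = FALSE])
  info <- data.frame(marker = map$marker[idx], chrom = map$chrom[idx],
                     bp = map$bp[idx], cm = map$cm[idx],
                     stringsAsFactors = FALSE)
  .new_marker_set("founder", "QTL_F", info, X, n, full = full)
}

#' Marker set for the ancestral haplotype model (QTL_H)
#'
#' @param hap_posterior a `haplotype_posterior`
#' @param keep optional marker names (e.g. from
#'   [filter_haplotype_markers()])
#' @return a `marker_set` whose per-marker design is the n x (h - 1)
#'   haplotype-probability matrix with the first haplotype dropped as
#'   reference
#' @export
haplotype_markers <- function(hap_posterior, keep = NULL) {
  mk <- hap_posterior$markers
  idx <- if (is.null(keep)) seq_len(nrow(mk)) else match(keep, mk$marker)
  if (anyNA(idx)) stop_invalid("unknown marker in keep")
  full <- hap_posterior$prob[idx]
  X <- lapply(full, function(m) m[, -1L, drop = FALSE])
  info <- mk[idx, c("marker", "chrom", "bp", "cm")]
  rownames(info) <- NULL
  .new_marker_set("haplotype", "QTL_H", info, X, nrow(full[[1]]), full = full)
}

#' Restrict a marker set to a subset of lines
#' @param markers a `marker_set`
#' @param lines integer or logical index of lines to keep
#' @export
subset_lines <- function(markers, lines) {
  markers$X <- lapply(markers$X, function(m) m[lines, , drop = FALSE])
  if (!is.null(markers$full))
    markers$full <- lapply(markers$full, function(m) m[lines, , drop = FALSE])
  markers$n <- nrow(markers$X[[1]])
  markers
}

## ---- core fit -------------------------------------------------------------

.h2_grid <- function(grid_step) seq(0, 0.99, by = grid_step)

# eigendecompose K (or identity when K is NULL) and rotate
.rotate <- function(K, n) {
  if (is.null(K)) return(list(U = NULL, lambda = rep(1, n)))
  e <- eigen(K, symmetric = TRUE)
  list(U = e$vectors, lambda = pmax(e$values, 0))
}

.rot <- function(U, x) if (is.null(U)) x else crossprod(U, x)

# run the compiled grid scan for one chromosome's markers
.scan_chrom <- function(Y, X0, Xlist, K, grid) {
  n <- nrow(Y)
  ro <- .rotate(K, n)
  if (is.null(ro$U)) grid <- 0
  Yt <- .rot(ro$U, Y)
  X0t <- .rot(ro$U, X0)
  Xt <- lapply(Xlist, function(x) .rot(ro$U, x))
  fit <- grid_lmm_scan(Yt, X0t, Xt, ro$lambda, grid)
  fit$grid <- grid
  fit$p0 <- ncol(X0)
  fit$n <- n
  fit
}

# p-values from one .scan_chrom result: list(lrt, p_lrt, p_f, h2) as
# markers x q matrices
.scan_pvalues <- function(fit) {
  q <- ncol(fit$ll0)
  nm <- nrow(fit$ll_alt)
  ll0max <- apply(fit$ll0, 2, max)
  lrt <- 2 * sweep(fit$ll_alt, 2, ll0max)
  lrt[lrt < 0] <- 0
  df <- as.integer(fit$df)
  p_lrt <- matrix(pchisq(lrt, rep(df, q), lower.tail = FALSE), nm, q)
  # F test at the marker's ML-optimal h2, null refit at the same h2
  rss0_at <- matrix(NA_real_, nm, q)
  gb <- fit$gbest
  okg <- gb > 0
  rss0_at[okg] <- fit$rss0[cbind(gb[okg], col(gb)[okg])]
  df2 <- fit$n - fit$p0 - df
  fstat <- (rss0_at - fit$rss_alt) / rep(df, q) / (fit$rss_alt / rep(df2, q))
  fstat[fstat < 0] <- 0
  p_f <- matrix(pf(fstat, rep(df, q), rep(df2, q), lower.tail = FALSE), nm, q)
  h2 <- matrix(NA_real_, nm, q)
  h2[okg] <- fit$grid[gb[okg]]
  bad <- !fit$ok
  if (any(bad)) { lrt[bad, ] <- NA; p_lrt[bad, ] <- NA; p_f[bad, ] <- NA }
  list(lrt = lrt, p_lrt = p_lrt, p_f = p_f, h2 = h2, df = df)
}

#' Fit the mixed model at a single marker
#'
#' @param y numeric response, one value per line
#' @param X n x p marker design (reference level already dropped)
#' @param K kinship matrix for the marker's chromosome, or NULL for a
#'   fixed-effects (OLS) fit
#' @param covariates optional n x c matrix of fixed covariates
#' @param grid_step grid resolution for the h2 profile (default 0.01)
#' @return list with `lrt`, `df`, `p_lrt`, `p_f`, `h2`, `beta`, `se`,
#'   `vcov`, `sigma2`
#' @export
fit_marker_lmm <- function(y, X, K = NULL, covariates = NULL,
                           grid_step = 0.01) {
  X <- as.matrix(X)
  keep_cols <- apply(X, 2, sd) > 0
  if (!any(keep_cols)) stop_invalid("marker design has no varying column")
  X <- X[, keep_cols, drop = FALSE]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  grid <- .h2_grid(grid_step)
  ro <- .rotate(K, n)
  if (is.null(ro$U)) grid <- 0
  Yt <- .rot(ro$U, matrix(y))
  X0t <- .rot(ro$U, X0)
  Xt <- .rot(ro$U, X)
  fit <- grid_lmm_scan(Yt, X0t, list(Xt), ro$lambda, grid)
  fit$grid <- grid; fit$p0 <- ncol(X0); fit$n <- n
  pv <- .scan_pvalues(fit)
  if (!fit$ok[1]) stop_invalid("marker design is rank deficient")
  h2 <- pv$h2[1, 1]
  w <- 1 / (h2 * ro$lambda + (1 - h2))
  Xf <- cbind(X0t, Xt)
  A <- crossprod(Xf * w, Xf)
  b <- crossprod(Xf * w, Yt)
  Ai <- solve(A)
  beta <- drop(Ai %*% b)
  rss <- fit$rss_alt[1, 1]
  sigma2 <- rss / (n - ncol(Xf))
  vcov <- sigma2 * Ai
  names(beta) <- colnames(Xf)
  dimnames(vcov) <- list(names(beta), names(beta))
  list(lrt = pv$lrt[1, 1], df = pv$df[1], p_lrt = pv$p_lrt[1, 1],
       p_f = pv$p_f[1, 1], h2 = h2, beta = beta,
       se = sqrt(diag(vcov)), vcov = vcov, sigma2 = sigma2)
}

#' Genome scan under one allelic model
#'
#' Applies the grid-profile mixed-model fit at every marker of a marker
#' set, using the leave-one-chromosome-out kinship of each marker's
#' chromosome. Markers with a degenerate (zero-variance or collinear)
#' design are skipped and recorded with NA statistics.
#'
#' @param y numeric response (one value per line, e.g. BLUPs), aligned
#'   with the marker set's lines
#' @param markers a `marker_set` (see [snp_markers()], [founder_markers()],
#'   [haplotype_markers()])
#' @param K_loco named list of per-chromosome kinship matrices from
#'   [compute_grm_loco()]; a single matrix is used for all chromosomes;
#'   NULL gives a fixed-effects scan
#' @param covariates optional fixed-covariate matrix
#' @param grid_step h2 grid resolution (default 0.01)
#' @param test `"lrt"` (likelihood-ratio chi-squared, default) or `"f"`
#'   (GLS F test at the ML-optimal h2)
#' @return a `magic_scan` data.frame: marker, chrom, bp, cm, model, df,
#'   lrt, p, neglog10p, h2
#' @export
genome_scan <- function(y, markers, K_loco = NULL, covariates = NULL,
                        grid_step = 0.01, test = c("lrt", "f")) {
  test <- match.arg(test)
  res <- .scan_engine(matrix(y), markers, K_loco, covariates, grid_step)
  p <- if (test == "lrt") res$p_lrt[, 1] else res$p_f[, 1]
  out <- cbind(markers$info,
               data.frame(model = markers$model, df = res$df,
                          lrt = res$lrt[, 1], p = p,
                          neglog10p = -log10(p), h2 = res$h2[, 1]))
  attr(out, "test") <- test
  class(out) <- c("magic_scan", "data.frame")
  out
}

# shared engine: Y may hold several response columns (permutations)
.scan_engine <- function(Y, markers, K_loco, covariates, grid_step) {
  n <- markers$n
  if (nrow(Y) != n) stop_invalid("response length does not match marker set")
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  grid <- .h2_grid(grid_step)
  info <- markers$info
  nm <- nrow(info)
  q <- ncol(Y)
  out <- list(lrt = matrix(NA_real_, nm, q), p_lrt = matrix(NA_real_, nm, q),
              p_f = matrix(NA_real_, nm, q), h2 = matrix(NA_real_, nm, q),
              df = integer(nm))
  for (cc in unique(info$chrom)) {
    jj <- which(info$chrom == cc)
    # drop zero-variance design columns (e.g. founders absent from the
    # population) before fitting; fully degenerate markers are skipped
    Xp <- lapply(markers$X[jj], function(m)
      m[, apply(m, 2, sd) > 0, drop = FALSE])
    nonzero <- vapply(Xp, ncol, 1L) > 0L
    use <- jj[nonzero]
    if (!length(use)) next
    K <- if (is.null(K_loco)) NULL
         else if (is.list(K_loco)) K_loco[[cc]] else K_loco
    fit <- .scan_chrom(Y, X0, Xp[nonzero], K, grid)
    pv <- .scan_pvalues(fit)
    out$lrt[use, ] <- pv$lrt
    out$p_lrt[use, ] <- pv$p_lrt
    out$p_f[use, ] <- pv$p_f
    out$h2[use, ] <- pv$h2
    out$df[use] <- pv$df
  }
  out
}

#' @export
print.magic_scan <- function(x, ...) {
  cat("Genome scan (", x$model[1], "): ", nrow(x), " markers, ",
      sum(is.na(x$p)), " skipped\n", sep = "")
  top <- x[which.max(x$neglog10p), ]
  if (nrow(top))
    cat("  top: ", top$marker, " (", top$chrom, ":", top$bp, ") -log10 p = ",
        round(top$neglog10p, 2), "\n", sep = "")
  invisible(x)
}

#' Genome-wide permutation significance threshold
#'
#' Shuffles the line labels linking phenotype to genotype rows (one shared
#' shuffle across all markers per permutation), records the genome-wide
#' maximum -log10 p of each permuted scan, and returns the (1 - alpha)
#' quantile of the maxima. Thresholds are model-specific: compute one per
#' marker set.
#'
#' @inheritParams genome_scan
#' @param n_perm number of permutations (>= 20; default 1000)
#' @param alpha genome-wide error rate (default 0.05)
#' @param seed optional RNG seed
#' @return list with `threshold` (on the -log10 p scale), `maxima`
#'   (per-permutation maxima), `alpha`, `n_perm`
#' @export
permutation_threshold <- function(y, markers, K_loco = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = NULL,
                                  covariates = NULL, grid_step = 0.01,
                                  test = c("lrt", "f")) {
  test <- match.arg(test)
  if (n_perm < 20) stop_invalid("n_perm must be >= 20")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must be in (0, 1)")
  set_seed_if(seed)
  n <- markers$n
  perms <- replicate(n_perm, sample.int(n))
  Y <- cbind(y, matrix(y[perms], n, n_perm))
  res <- .scan_engine(Y, markers, K_loco, covariates, grid_step)
  P <- if (test == "lrt") res$p_lrt else res$p_f
  nlp <- -log10(P)
  maxima <- apply(nlp[, -1, drop = FALSE], 2, max, na.rm = TRUE)
  list(threshold = unname(quantile(maxima, 1 - alpha, type = 7)),
       maxima = maxima, alpha = alpha, n_perm = n_perm,
       observed_max = max(nlp[, 1], na.rm = TRUE))
}
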