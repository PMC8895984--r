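# QTL support intervals, cross-model merging, masked effect sizes, and
# conditional scans.

#' Support interval around a scan peak
#'
#' The interval runs from the left-most to the right-most tested marker
#' inside a window of `window_mb` megabases centered on the peak (same
#' chromosome) whose -log10 p is within `drop` units of the peak's.
#'
#' @param scan a `magic_scan`
#' @param peak_marker marker name of the peak; defaults to the scan's most
#'   significant marker
#' @param window_mb total window width in Mb (default 100, i.e. +/- 50 Mb)
#' @param drop -log10 p drop defining the bounds (default 2)
#' @param phenotype,environment optional labels carried into the record
#' @return a one-row `qtl_record` data.frame: phenotype, environment,
#'   model, chrom, peak_marker, peak_bp, peak_cm, peak_neglog10p,
#'   start_bp, end_bp, start_cm, end_cm
#' @export
support_interval <- function(scan, peak_marker = NULL, window_mb = 100,
                             drop = 2, phenotype = NA_character_,
                             environment = NA_character_) {
  ok <- !is.na(scan$neglog10p)
  if (!any(ok)) stop_invalid("scan has no usable markers")
  if (is.null(peak_marker)) {
    pk <- which.max(ifelse(ok, scan$neglog10p, -Inf))
  } else {
    pk <- match(peak_marker, scan$marker)
    if (is.na(pk)) stop_invalid("peak marker not in scan")
  }
  half <- window_mb / 2 * 1e6
  inwin <- ok & scan$chrom == scan$chrom[pk] &
    abs(scan$bp - scan$bp[pk]) <= half
  sel <- inwin & scan$neglog10p >= scan$neglog10p[pk] - drop
  out <- data.frame(phenotype = phenotype, environment = environment,
                    model = scan$model[pk], chrom = scan$chrom[pk],
                    peak_marker = scan$marker[pk], peak_bp = scan$bp[pk],
                    peak_cm = scan$cm[pk],
                    peak_neglog10p = scan$neglog10p[pk],
                    start_bp = min(scan$bp[sel]), end_bp = max(scan$bp[sel]),
                    start_cm = min(scan$cm[sel]), end_cm = max(scan$cm[sel]),
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_record", "data.frame")
  out
}

#' Merge QTL records across models and environments
#'
#' Records of the same phenotype whose support intervals overlap by at
#' least 1 bp are merged into one QTL (transitively), with the union
#' interval and the list of contributing (model, environment, peak)
#' members.
#'
#' @param records a data.frame of `qtl_record` rows (rbind them)
#' @return data.frame with one row per merged QTL: `qtl_id`, `phenotype`,
#'   `chrom`, `start_bp`, `end_bp`, `n_members`, `models`, `environments`,
#'   `best_peak_marker`, `best_neglog10p`, plus a `members` list-column of
#'   row indices into `records`
#' @export
merge_qtl <- function(records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (!n) return(records)
  key <- paste(records$phenotype, records$chrom)
  comp <- integer(n)
  nextid <- 0L
  for (kk in unique(key)) {
    ii <- which(key == kk)
    ord <- ii[order(records$start_bp[ii])]
    cur_end <- -Inf
    for (i in ord) {
      if (records$start_bp[i] <= cur_end) {
        comp[i] <- nextid
        cur_end <- max(cur_end, records$end_bp[i])
      } else {
        nextid <- nextid + 1L
        comp[i] <- nextid
        cur_end <- records$end_bp[i]
      }
    }
  }
  out <- do.call(rbind, lapply(sort(unique(comp)), function(id) {
    mm <- which(comp == id)
    best <- mm[which.max(records$peak_neglog10p[mm])]
    data.frame(qtl_id = id, phenotype = records$phenotype[mm[1]],
               chrom = records$chrom[mm[1]],
               start_bp = min(records$start_bp[mm]),
               end_bp = max(records$end_bp[mm]),
               n_members = length(mm),
               models = paste(sort(unique(records$model[mm])), collapse = ","),
               environments = paste(sort(unique(records$environment[mm])),
                                    collapse = ","),
               best_peak_marker = records$peak_marker[best],
               best_neglog10p = records$peak_neglog10p[best],
               stringsAsFactors = FALSE)
  }))
  out$members <- lapply(sort(unique(comp)), function(id) which(comp == id))
  rownames(out) <- NULL
  out
}

#' Mean-relative effect sizes with low-count masking
#'
#' Refits the marker model with the full level-probability design
#' (reference column dropped for fitting), re-parameterizes the estimates
#' as deviations from the population mean, and masks the effect of any
#' level carried by fewer than `min_lines` lines at probability greater
#' than `prob_threshold`.
#'
#' @param y numeric response per line
#' @param design n x k matrix of level probabilities (founder or haplotype
#'   columns, or ref/alt columns for a SNP), with column names
#' @param K kinship matrix for the marker's chromosome (NULL for OLS)
#' @param min_lines minimum confident carrier count (default 5)
#' @param prob_threshold probability defining a confident carrier
#'   (default 0.8)
#' @param covariates optional fixed covariates
#' @param grid_step h2 grid resolution
#' @return data.frame with one row per level: `level`, `n_lines`,
#'   `effect`, `se`, `masked`. Masked effects are reported as NA.
#' @export
estimate_effect_sizes <- function(y, design, K = NULL, min_lines = 5,
                                  prob_threshold = 0.8, covariates = NULL,
                                  grid_step = 0.01) {
  design <- as.matrix(design)
  k <- ncol(design)
  levels <- colnames(design) %||% paste0("A", seq_len(k))
  n_lines <- colSums(design > prob_threshold)
  fit <- fit_marker_lmm(y, design[, -1L, drop = FALSE], K = K,
                        covariates = covariates, grid_step = grid_step)
  # level means: mu_1 = intercept, mu_j = intercept + beta_j
  bn <- names(fit$beta)
  coef_of <- function(lv) if (lv %in% bn) fit$beta[[lv]] else 0
  betas <- vapply(levels, coef_of, 1)          # beta_1 = 0 (reference)
  pbar <- colMeans(design)
  pbar <- pbar / sum(pbar)
  effects <- betas - sum(pbar * betas)
  # SE of each mean-relative effect via the coefficient covariance
  nb <- setdiff(bn, "(Intercept)")
  V <- fit$vcov[nb, nb, drop = FALSE]
  se <- vapply(levels, function(lv) {
    cvec <- as.numeric(nb == lv) - pbar[match(nb, levels)]
    sqrt(drop(t(cvec) %*% V %*% cvec))
  }, 1)
  masked <- n_lines < min_lines
  if (all(masked)) warning("all levels masked by the low-count rule")
  out <- data.frame(level = levels, n_lines = as.integer(n_lines),
                    effect = ifelse(masked, NA_real_, effects),
                    se = ifelse(masked, NA_real_, se),
                    masked = masked, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Conditional scan within a support interval
#'
#' Re-scans the markers of a support interval with the top marker's design
#' included as a fixed covariate; a second QTL is declared only if some
#' marker still exceeds the genome-wide threshold. Markers whose design is
#' collinear with the covariate (including the top marker itself) are
#' skipped and reported with NA.
#'
#' @inheritParams genome_scan
#' @param top_marker marker name whose design becomes the covariate
#' @param interval optional `qtl_record` (or any data.frame with `chrom`,
#'   `start_bp`, `end_bp`) restricting the tested markers; default is the
#'   top marker's chromosome
#' @return a `magic_scan` over the interval markers
#' @export
conditional_scan <- function(y, markers, K_loco = NULL, top_marker,
                             interval = NULL, grid_step = 0.01,
                             test = c("lrt", "f")) {
  test <- match.arg(test)
  it <- match(top_marker, markers$info$marker)
  if (is.na(it)) stop_invalid("top marker not in marker set")
  cov <- markers$X[[it]]
  cov <- cov[, apply(cov, 2, sd) > 0, drop = FALSE]
  colnames(cov) <- paste0("cond_", seq_len(ncol(cov)))
  info <- markers$info
  sel <- info$chrom == info$chrom[it]
  if (!is.null(interval))
    sel <- sel & info$bp >= interval$start_bp[1] & info$bp <= interval$end_bp[1]
  sub <- markers
  sub$X <- markers$X[sel]
  sub$full <- markers$full[sel]
  sub$info <- info[sel, , drop = FALSE]
  genome_scan(y, sub, K_loco = K_loco, covariates = cov,
              grid_step = grid_step, test = test)
}
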