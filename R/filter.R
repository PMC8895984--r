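# Iterative R^2 thinning of probability markers.
#
# The redundancy measure between two markers' probability matrices
# (lines x alleles, equal width) is the squared Pearson correlation of the
# two column-centered matrices flattened to vectors; it is symmetric, lies
# in [0, 1], and reduces to the squared allelic correlation when f = 2.

#' Squared correlation between two probability matrices
#'
#' @param a,b numeric matrices of identical dimension
#' @return squared Pearson correlation of the column-centered, flattened
#'   matrices. If either centered matrix is constant (an uninformative
#'   marker) the markers are treated as perfectly redundant and 1 is
#'   returned.
#' @export
prob_r2 <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_invalid("matrices must have equal dimension")
  va <- as.vector(a) - rep(colMeans(a), each = nrow(a))
  vb <- as.vector(b) - rep(colMeans(b), each = nrow(b))
  if (all(va == 0) || all(vb == 0)) return(1)
  cor(va, vb)^2
}

# greedy left-to-right sweep: within each run of consecutive items sharing
# a stratum, keep the first; keep the next item only if its R^2 with the
# last KEPT item is <= threshold
.sweep_filter <- function(mats, strata, r2_threshold) {
  stopifnot(length(mats) == length(strata))
  keep <- logical(length(mats))
  run <- cumsum(c(TRUE, strata[-1L] != strata[-length(strata)]))
  for (rr in unique(run)) {
    ii <- which(run == rr)
    last <- ii[1L]
    keep[last] <- TRUE
    for (j in ii[-1L]) {
      if (prob_r2(mats[[last]], mats[[j]]) <= r2_threshold) {
        keep[j] <- TRUE
        last <- j
      }
    }
  }
  keep
}

#' Thin founder-probability markers by iterative R^2 filtering
#'
#' Sweeps each chromosome left to right, keeping the first marker and
#' dropping any subsequent marker whose probability matrix has R^2 greater
#' than `r2_threshold` with the last kept marker. The sweep is idempotent:
#' filtering an already-filtered set removes nothing.
#'
#' @param posterior a `founder_posterior`
#' @param r2_threshold drop threshold in (0, 1] (default 0.95)
#' @return character vector of kept marker names
#' @export
filter_probability_markers <- function(posterior, r2_threshold = 0.95) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_invalid("r2_threshold must be in (0, 1]")
  map <- attr(posterior, "map")
  mats <- lapply(seq_len(dim(posterior)[2]), function(j)
    matrix(posterior[, j, ], dim(posterior)[1], dim(posterior)[3]))
  keep <- .sweep_filter(mats, map$chrom, r2_threshold)
  map$marker[keep]
}
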