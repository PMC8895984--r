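# Genetic maps: marker tables with physical (bp) and genetic (cM) coordinates.
#
# Internally all bp intervals are 0-based, half-open [start, end). A map
# carries the chromosome extents as attributes so that mosaics can tile the
# full chromosome even beyond the terminal markers.

#' Construct a genetic map
#'
#' @param markers data.frame with columns `chrom`, `marker`, `bp`, `cm`.
#'   Within each chromosome `bp` and `cm` must be non-decreasing.
#' @param chrom_len_bp,chrom_len_cm named numeric vectors of chromosome
#'   extents; default to just past the last marker.
#' @return An object of class `genetic_map` (a data.frame with extent
#'   attributes).
#' @export
genetic_map <- function(markers, chrom_len_bp = NULL, chrom_len_cm = NULL) {
  need <- c("chrom", "marker", "bp", "cm")
  if (!all(need %in% names(markers)))
    stop_invalid("map must have columns ", paste(need, collapse = ", "))
  markers$chrom <- as.character(markers$chrom)
  markers$marker <- as.character(markers$marker)
  if (anyDuplicated(markers$marker))
    stop_invalid("duplicated marker names in map")
  chroms <- unique(markers$chrom)
  for (cc in chroms) {
    mm <- markers[markers$chrom == cc, ]
    if (nrow(mm) < 2L)
      stop_invalid("chromosome ", cc, " has fewer than 2 markers")
    if (is.unsorted(mm$bp) || is.unsorted(mm$cm))
      stop_invalid("bp/cM must be non-decreasing within chromosome ", cc)
    if (any(mm$cm < 0)) stop_invalid("negative cM position on chromosome ", cc)
  }
  if (is.null(chrom_len_bp))
    chrom_len_bp <- tapply(markers$bp, markers$chrom, max)[chroms] + 1
  if (is.null(chrom_len_cm))
    chrom_len_cm <- tapply(markers$cm, markers$chrom, max)[chroms]
  chrom_len_bp <- setNames(as.numeric(chrom_len_bp), chroms)
  chrom_len_cm <- setNames(as.numeric(chrom_len_cm), chroms)
  rownames(markers) <- markers$marker
  out <- structure(markers,
                   chrom_len_bp = chrom_len_bp,
                   chrom_len_cm = chrom_len_cm,
                   class = c("genetic_map", "data.frame"))
  # precompute interpolation anchors once; meiosis queries them heavily
  anchors <- lapply(chroms, function(cc) .map_anchors(out, cc))
  names(anchors) <- chroms
  attr(out, "anchors") <- anchors
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(map_chromosomes(x)), "chromosome(s),",
      nrow(x), "markers\n")
  cat("  total length:", round(sum(attr(x, "chrom_len_cm")), 1), "cM /",
      format(sum(attr(x, "chrom_len_bp")), big.mark = ","), "bp\n")
  invisible(x)
}

#' Chromosome identifiers of a map
#' @param map a `genetic_map`
#' @export
map_chromosomes <- function(map) names(attr(map, "chrom_len_bp"))

#' Chromosome extents of a map
#' @param map a `genetic_map`
#' @param units `"bp"` or `"cm"`
#' @export
chrom_lengths <- function(map, units = c("bp", "cm")) {
  units <- match.arg(units)
  if (units == "bp") attr(map, "chrom_len_bp") else attr(map, "chrom_len_cm")
}

# anchor points for piecewise-linear cm <-> bp interpolation on one chromosome
.map_anchors <- function(map, chrom) {
  cached <- attr(map, "anchors")
  if (!is.null(cached) && !is.null(cached[[chrom]])) return(cached[[chrom]])
  mm <- map[map$chrom == chrom, , drop = FALSE]
  len_bp <- attr(map, "chrom_len_bp")[[chrom]]
  len_cm <- attr(map, "chrom_len_cm")[[chrom]]
  bp <- c(0, mm$bp, len_bp)
  cm <- c(0, mm$cm, len_cm)
  # drop anchors that would break monotonicity (e.g. terminal marker at the
  # chromosome end); approx() handles remaining ties with ties = "ordered"
  keep <- c(TRUE, diff(bp) >= 0 & diff(cm) >= 0)
  list(bp = cummax(bp)[keep], cm = cummax(cm)[keep])
}

#' Interpolate genetic position to physical position
#'
#' Piecewise-linear interpolation between map markers (with the chromosome
#' ends as extra anchors).
#' @param map a `genetic_map`
#' @param chrom chromosome id
#' @param cm genetic positions (cM)
#' @return physical positions in bp
#' @export
cm_to_bp <- function(map, chrom, cm) {
  a <- .map_anchors(map, chrom)
  if (length(cm) == 0L) return(numeric(0))
  approx(a$cm, a$bp, xout = cm, rule = 2, ties = "ordered")$y
}

#' Interpolate physical position to genetic position
#' @rdname cm_to_bp
#' @param bp physical positions (bp)
#' @export
bp_to_cm <- function(map, chrom, bp) {
  a <- .map_anchors(map, chrom)
  if (length(bp) == 0L) return(numeric(0))
  approx(a$bp, a$cm, xout = bp, rule = 2, ties = "ordered")$y
}

#' Simulate a genetic map
#'
#' Markers are placed at sorted uniform positions on both the physical and
#' the genetic axis, so local recombination rate varies along the chromosome
#' while cM remains monotone with bp.
#'
#' @param n_chrom number of chromosomes (>= 1)
#' @param n_markers markers per chromosome (scalar or vector, each >= 2)
#' @param cm_len genetic length per chromosome in cM (> 0)
#' @param bp_len physical length per chromosome in bp (> 0)
#' @param seed optional RNG seed
#' @return a `genetic_map`
#' @examples
#' map <- simulate_map(2, 100, 150, 3e8, seed = 1)
#' @export
simulate_map <- function(n_chrom, n_markers, cm_len, bp_len, seed = NULL) {
  set_seed_if(seed)
  if (n_chrom < 1) stop_invalid("n_chrom must be >= 1")
  n_markers <- rep_len(n_markers, n_chrom)
  cm_len <- rep_len(cm_len, n_chrom)
  bp_len <- rep_len(bp_len, n_chrom)
  if (any(n_markers < 2)) stop_invalid("need at least 2 markers per chromosome")
  if (any(cm_len <= 0) || any(bp_len <= 0))
    stop_invalid("chromosome lengths must be positive")
  out <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    m <- n_markers[i]
    bp <- sort(ceiling(runif(m, 0, bp_len[i] - 1)))
    bp <- bp + seq_len(m) - 1  # break coincident draws, keep order
    bp <- pmin(bp, bp_len[i] - 1)
    cm <- sort(runif(m, 0, cm_len[i]))
    out[[i]] <- data.frame(chrom = paste0("chr", i),
                           marker = sprintf("S%d_%d", i, seq_len(m)),
                           bp = bp, cm = cm,
                           stringsAsFactors = FALSE)
  }
  genetic_map(do.call(rbind, out),
              chrom_len_bp = setNames(bp_len, paste0("chr", seq_len(n_chrom))),
              chrom_len_cm = setNames(cm_len, paste0("chr", seq_len(n_chrom))))
}
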