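# Ancestry mosaics and meiosis.
#
# A mosaic stores one haploid genome as, per chromosome, a matrix with
# columns (start, end, founder): 0-based half-open bp segments labelled by
# founder index. Segments tile each chromosome exactly and adjacent
# segments carry distinct founders.

#' Single-founder ancestry mosaic
#'
#' @param founder founder index (1-based)
#' @param map a `genetic_map`
#' @return an `ancestry_mosaic`
#' @export
founder_mosaic <- function(founder, map) {
  lens <- chrom_lengths(map, "bp")
  segs <- lapply(lens, function(L)
    matrix(c(0, L, founder), nrow = 1,
           dimnames = list(NULL, c("start", "end", "founder"))))
  structure(segs, class = "ancestry_mosaic")
}

#' @export
print.ancestry_mosaic <- function(x, ...) {
  cat("Ancestry mosaic:", length(x), "chromosome(s),",
      sum(vapply(x, nrow, 1L)), "segment(s),",
      crossover_count(x), "junction(s)\n")
  invisible(x)
}

#' Convert a mosaic to a segment data.frame
#' @param x an `ancestry_mosaic`
#' @param founder_names optional founder ids to label segments
#' @param ... unused
#' @export
as.data.frame.ancestry_mosaic <- function(x, founder_names = NULL, ...) {
  out <- do.call(rbind, lapply(names(x), function(cc) {
    data.frame(chrom = cc, start = x[[cc]][, 1], end = x[[cc]][, 2],
               founder = x[[cc]][, 3], stringsAsFactors = FALSE)
  }))
  if (!is.null(founder_names)) out$founder <- founder_names[out$founder]
  rownames(out) <- NULL
  out
}

#' Number of ancestry junctions in a mosaic
#' @param mosaic an `ancestry_mosaic`
#' @export
crossover_count <- function(mosaic) {
  sum(vapply(mosaic, nrow, 1L) - 1L)
}

#' Founder of origin at given positions
#' @param mosaic an `ancestry_mosaic`
#' @param chrom chromosome id
#' @param bp physical positions
#' @return integer founder indices
#' @export
mosaic_founder_at <- function(mosaic, chrom, bp) {
  seg <- mosaic[[chrom]]
  seg[.interval_index(bp, seg[, 1]), 3]
}

#' Simulate one meiosis
#'
#' Produces a gamete mosaic from a pair of parental haplotype mosaics.
#' Crossovers follow a Poisson process with rate 1 per Morgan on the
#' genetic (cM) axis (Haldane, no interference); crossover positions are
#' mapped back to bp by piecewise-linear interpolation of the map. The
#' starting haplotype of each chromosome is chosen at random.
#'
#' @param parents list of two `ancestry_mosaic` objects (the parental
#'   haplotypes), or a single mosaic given twice for an inbred parent
#' @param map a `genetic_map`
#' @param seed optional RNG seed
#' @return an `ancestry_mosaic` (the gamete)
#' @export
meiosis <- function(parents, map, seed = NULL) {
  set_seed_if(seed)
  h1 <- parents[[1]]; h2 <- parents[[2]]
  chroms <- map_chromosomes(map)
  if (!identical(names(h1), chroms) || !identical(names(h2), chroms))
    stop_invalid("parental mosaics do not tile the same map")
  len_bp <- attr(map, "chrom_len_bp")
  len_cm <- attr(map, "chrom_len_cm")
  anchors <- attr(map, "anchors") %||%
    setNames(lapply(chroms, function(cc) .map_anchors(map, cc)), chroms)
  out <- meiosis_cpp(unclass(h1), unclass(h2), len_bp, len_cm,
                     lapply(anchors, `[[`, "cm"),
                     lapply(anchors, `[[`, "bp"))
  structure(out, class = "ancestry_mosaic")
}
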