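# Ancestral haplotype blocks.
#
# Block boundaries are the sorted unique endpoints of all pairwise IBD
# segments plus the chromosome ends, so within a block every segment either
# covers it entirely or not at all. Within a block, founders are grouped
# into ancestral haplotypes as the connected components of the graph whose
# edges are the covering IBD pairs (the transitive-closure assumption); a
# block is flagged "incomplete" when some component is not a clique, i.e.
# not all of its founder pairs were themselves called IBD.

#' Build haplotype blocks from pairwise IBD segments
#'
#' @param segments an `ibd_segments` data.frame (may be empty)
#' @param map a `genetic_map`
#' @param founder_ids founder ids, in index order
#' @return object of class `haplotype_blocks`: list with `blocks` (one row
#'   per block: `chrom`, `start_bp`, `end_bp`, `start_cm`, `end_cm`,
#'   `n_hap`, `incomplete`) and `groups` (per block, an integer vector
#'   mapping each founder to its haplotype group, groups numbered by their
#'   lowest founder index)
#' @export
build_haplotype_blocks <- function(segments, map, founder_ids) {
  f <- length(founder_ids)
  len_bp <- chrom_lengths(map, "bp")
  blk <- list(); grp <- list()
  for (cc in map_chromosomes(map)) {
    seg <- segments[segments$chrom == cc, , drop = FALSE]
    if (nrow(seg)) {
      if (any(seg$start_bp < 0 | seg$end_bp > len_bp[[cc]]))
        stop_invalid("IBD segment outside chromosome ", cc)
    }
    bounds <- sort(unique(c(0, len_bp[[cc]], seg$start_bp, seg$end_bp)))
    bounds <- bounds[bounds >= 0 & bounds <= len_bp[[cc]]]
    for (k in seq_len(length(bounds) - 1L)) {
      b0 <- bounds[k]; b1 <- bounds[k + 1L]
      if (b1 <= b0) next  # zero-length blocks dropped
      cover <- seg$start_bp <= b0 & seg$end_bp >= b1
      gg <- .founder_components(seg[cover, , drop = FALSE], founder_ids)
      blk[[length(blk) + 1L]] <- data.frame(
        chrom = cc, start_bp = b0, end_bp = b1,
        start_cm = bp_to_cm(map, cc, b0), end_cm = bp_to_cm(map, cc, b1),
        n_hap = max(gg$membership), incomplete = gg$incomplete,
        stringsAsFactors = FALSE)
      grp[[length(blk)]] <- gg$membership
    }
  }
  blocks <- do.call(rbind, blk)
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, groups = grp, founder_ids = founder_ids),
            class = "haplotype_blocks")
}

# connected components over founders from covering segments; groups
# renumbered by lowest founder index; incomplete = some component not a
# clique of called pairs
.founder_components <- function(cover, founder_ids) {
  f <- length(founder_ids)
  if (!nrow(cover)) {
    return(list(membership = setNames(seq_len(f), founder_ids),
                incomplete = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = cover$founder1, to = cover$founder2),
    directed = FALSE, vertices = data.frame(name = founder_ids))
  comp <- igraph::components(g)
  memb <- comp$membership[founder_ids]
  # renumber groups in order of first (lowest-index) founder
  first <- tapply(seq_len(f), memb, min)
  relab <- rank(first)
  memb <- as.integer(relab[as.character(memb)])
  names(memb) <- founder_ids
  n_edges <- nrow(unique(cover[, c("founder1", "founder2")]))
  sizes <- tabulate(memb)
  incomplete <- n_edges < sum(choose(sizes, 2))
  list(membership = memb, incomplete = incomplete)
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat("Haplotype block set:", nrow(x$blocks), "blocks,",
      length(x$founder_ids), "founders\n")
  cat("  mean haplotypes per block:", round(mean(x$blocks$n_hap), 2),
      "| incomplete-graph fraction:",
      round(mean(x$blocks$incomplete), 3), "\n")
  invisible(x)
}

# group vector of the block containing (chrom, bp)
.block_grouping_at <- function(blocks, chrom, bp) {
  b <- blocks$blocks
  sel <- which(b$chrom == chrom & b$start_bp <= bp & b$end_bp > bp)
  if (!length(sel)) stop_invalid("position ", chrom, ":", bp,
                                 " outside all haplotype blocks")
  blocks$groups[[sel[1L]]]
}

#' Sum founder probabilities into haplotype probabilities
#'
#' Per marker, the probability of each ancestral haplotype is the sum of
#' the posterior probabilities of its member founders, with membership
#' taken from the block enclosing the marker. Total probability mass per
#' (line, marker) is conserved.
#'
#' @param posterior a `founder_posterior`
#' @param blocks a `haplotype_blocks` object
#' @return object of class `haplotype_posterior`: list with `prob` (per
#'   marker, a lines x n_hap matrix) and `markers` (marker table with the
#'   enclosing block index and `n_hap`)
#' @export
haplotype_probabilities <- function(posterior, blocks) {
  map <- attr(posterior, "map")
  b <- blocks$blocks
  n <- dim(posterior)[1]; M <- dim(posterior)[2]; f <- dim(posterior)[3]
  block_idx <- integer(M)
  for (cc in map_chromosomes(map)) {
    mi <- which(map$chrom == cc)
    bi <- which(b$chrom == cc)
    if (!length(bi)) stop_invalid("no haplotype blocks on chromosome ", cc)
    pos <- findInterval(map$bp[mi], b$start_bp[bi])
    if (any(pos < 1) || any(map$bp[mi] >= b$end_bp[bi[length(bi)]]))
      stop_invalid("marker outside all haplotype blocks on ", cc)
    block_idx[mi] <- bi[pos]
  }
  prob <- vector("list", M)
  for (j in seq_len(M)) {
    g <- blocks$groups[[block_idx[j]]]
    h <- max(g)
    ind <- matrix(0, f, h)
    ind[cbind(seq_len(f), g)] <- 1
    pm <- matrix(posterior[, j, ], n, f) %*% ind
    colnames(pm) <- paste0("H", seq_len(h))
    rownames(pm) <- dimnames(posterior)[[1]]
    prob[[j]] <- pm
  }
  markers <- data.frame(marker = map$marker, chrom = map$chrom,
                        bp = map$bp, cm = map$cm, block = block_idx,
                        n_hap = b$n_hap[block_idx],
                        stringsAsFactors = FALSE)
  structure(list(prob = prob, markers = markers, blocks = blocks),
            class = "haplotype_posterior")
}

#' Thin haplotype-probability markers by iterative R^2 filtering
#'
#' The greedy sweep of [filter_probability_markers()], applied separately
#' within runs of consecutive markers whose enclosing blocks share the
#' same number of distinct haplotypes (probability matrices of unequal
#' width are never compared); a new run also starts at each chromosome
#' boundary.
#'
#' @param hap_posterior a `haplotype_posterior`
#' @param r2_threshold drop threshold in (0, 1] (default 0.95)
#' @return character vector of kept marker names
#' @export
filter_haplotype_markers <- function(hap_posterior, r2_threshold = 0.95) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_invalid("r2_threshold must be in (0, 1]")
  mk <- hap_posterior$markers
  strata <- paste(mk$chrom, mk$n_hap)
  keep <- .sweep_filter(hap_posterior$prob, strata, r2_threshold)
  mk$marker[keep]
}

#' Summary statistics of a haplotype block set
#'
#' @param blocks a `haplotype_blocks` object
#' @return list with `per_chrom` and `genome` data.frames reporting block
#'   counts, physical and genetic size distributions, the distribution of
#'   haplotypes per block, and the incomplete-graph fraction
#' @export
block_summary <- function(blocks) {
  b <- blocks$blocks
  b$size_bp <- b$end_bp - b$start_bp
  b$size_cm <- b$end_cm - b$start_cm
  summarize <- function(d) data.frame(
    n_blocks = nrow(d),
    mean_bp = mean(d$size_bp), median_bp = median(d$size_bp),
    mean_cm = mean(d$size_cm), median_cm = median(d$size_cm),
    mean_n_hap = mean(d$n_hap), min_n_hap = min(d$n_hap),
    max_n_hap = max(d$n_hap),
    incomplete_fraction = mean(d$incomplete))
  per <- do.call(rbind, lapply(split(b, b$chrom), summarize))
  per <- cbind(chrom = rownames(per), per)
  rownames(per) <- NULL
  list(per_chrom = per, genome = summarize(b))
}
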