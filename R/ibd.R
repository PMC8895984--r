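# Pairwise identity-by-descent between founders.
#
# The internal caller is a deliberately simple run-based detector standing
# behind the module surface (the probabilistic machinery of dedicated IBD
# software is out of scope; externally computed segments can be ingested
# with read_ibd_segments): maximal runs of identical alleles are seeded,
# neighbouring runs are merged while the allele identity over the merged
# span stays at or above `identity_threshold` and the span stays within
# `window_cm`, and merged segments shorter than `min_len_cm` are dropped.

.new_ibd_segments <- function(df) {
  cols <- c("founder1", "founder2", "chrom", "start_bp", "end_bp",
            "start_cm", "end_cm")
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ibd_segments", "data.frame"))
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat("IBD segment set:", nrow(x), "segments,",
      length(unique(c(x$founder1, x$founder2))), "founders\n")
  invisible(x)
}

#' Detect pairwise IBD segments between founders
#'
#' @param founders a `founder_set`
#' @param map a `genetic_map` (defaults to the founders' map)
#' @param window_cm maximum span (cM) over which neighbouring identical
#'   runs may be merged (default 10)
#' @param min_len_cm minimum segment length in cM (default 0.2)
#' @param identity_threshold minimum allele identity within a segment
#'   (default 0.99)
#' @return an `ibd_segments` data.frame (founder1 < founder2 by index;
#'   `start_bp`/`end_bp` are the positions of the first and last matching
#'   marker)
#' @export
detect_pairwise_ibd <- function(founders, map = NULL, window_cm = 10,
                                min_len_cm = 0.2, identity_threshold = 0.99) {
  map <- map %||% founders$map
  if (!(window_cm > min_len_cm && min_len_cm > 0))
    stop_invalid("need window_cm > min_len_cm > 0")
  ids <- founder_ids(founders)
  f <- length(ids)
  res <- list()
  for (cc in map_chromosomes(map)) {
    idx <- which(map$chrom == cc)
    if (length(idx) < 2L) {
      warning("chromosome ", cc, " has fewer than 2 markers; skipped")
      next
    }
    bp <- map$bp[idx]; cm <- map$cm[idx]
    g <- founders$geno[, idx, drop = FALSE]
    for (a in seq_len(f - 1L)) for (b in seq((a + 1L), f)) {
      eq <- g[a, ] == g[b, ]
      segs <- .call_ibd_runs(eq, bp, cm, window_cm, min_len_cm,
                             identity_threshold)
      if (!is.null(segs) && nrow(segs)) {
        segs$founder1 <- ids[a]; segs$founder2 <- ids[b]; segs$chrom <- cc
        res[[length(res) + 1L]] <- segs
      }
    }
  }
  if (!length(res))
    return(.new_ibd_segments(data.frame(founder1 = character(0),
                                        founder2 = character(0),
                                        chrom = character(0), start_bp = numeric(0),
                                        end_bp = numeric(0), start_cm = numeric(0),
                                        end_cm = numeric(0))))
  .new_ibd_segments(do.call(rbind, res))
}

.call_ibd_runs <- function(eq, bp, cm, window_cm, min_len_cm, thr) {
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  # greedy merge of identical runs while identity over the merged span
  # holds and the bridged span stays within window_cm
  cur_s <- starts[runs[1L]]; cur_e <- ends[runs[1L]]
  out_s <- integer(0); out_e <- integer(0)
  for (k in runs[-1L]) {
    cand_e <- ends[k]
    span_ident <- mean(eq[cur_s:cand_e])
    if (span_ident >= thr && (cm[cand_e] - cm[cur_s]) <= window_cm) {
      cur_e <- cand_e
    } else {
      out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
  len_cm <- cm[out_e] - cm[out_s]
  keep <- len_cm >= min_len_cm
  if (!any(keep)) return(NULL)
  data.frame(start_bp = bp[out_s[keep]], end_bp = bp[out_e[keep]],
             start_cm = cm[out_s[keep]], end_cm = cm[out_e[keep]],
             stringsAsFactors = FALSE)
}

#' Read IBD segments from a whitespace-delimited file
#'
#' Accepts either a simple five-column layout (`founder1 founder2 chrom
#' start_bp end_bp`, with optional `start_cm end_cm`) or the nine-column
#' RefinedIBD layout (`ID1 HAP1 ID2 HAP2 CHROM START END LOD LENGTH_CM`).
#' Pairs are orientation-normalized to founder1 < founder2.
#'
#' @param path file path
#' @param founder_ids optional vector of valid founder ids, in index
#'   order; unknown founders are rejected
#' @return an `ibd_segments` data.frame
#' @export
read_ibd_segments <- function(path, founder_ids = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  has_header <- length(lines) > 0 &&
    grepl("founder1|^ID1", trimws(lines[1]), ignore.case = TRUE)
  if (has_header) lines <- lines[-1L]
  if (!length(lines))
    return(.new_ibd_segments(data.frame(founder1 = character(0),
                                        founder2 = character(0),
                                        chrom = character(0), start_bp = numeric(0),
                                        end_bp = numeric(0), start_cm = numeric(0),
                                        end_cm = numeric(0))))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  parse_row <- function(x, i) {
    ln <- i + has_header
    if (length(x) == 9L) {          # RefinedIBD layout
      x <- x[c(1, 3, 5, 6, 7)]
    } else if (length(x) < 5L || length(x) > 7L) {
      stop_invalid("malformed IBD segment file at line ", ln,
                   ": expected 5-7 or 9 fields, got ", length(x))
    }
    s <- suppressWarnings(as.numeric(x[4])); e <- suppressWarnings(as.numeric(x[5]))
    if (is.na(s) || is.na(e) || e <= s)
      stop_invalid("malformed IBD segment file at line ", ln,
                   ": bad coordinates")
    c(x[1], x[2], x[3], x[4], x[5],
      if (length(x) >= 7L) x[6:7] else c(NA, NA))
  }
  rows <- t(mapply(parse_row, fields, seq_along(fields)))
  df <- data.frame(founder1 = rows[, 1], founder2 = rows[, 2],
                   chrom = rows[, 3],
                   start_bp = as.numeric(rows[, 4]),
                   end_bp = as.numeric(rows[, 5]),
                   start_cm = suppressWarnings(as.numeric(rows[, 6])),
                   end_cm = suppressWarnings(as.numeric(rows[, 7])),
                   stringsAsFactors = FALSE)
  if (any(df$founder1 == df$founder2))
    stop_invalid("IBD segment pairs a founder with itself")
  if (!is.null(founder_ids)) {
    bad <- setdiff(unique(c(df$founder1, df$founder2)), founder_ids)
    if (length(bad))
      stop_invalid("unknown founder id(s) in IBD file: ",
                   paste(bad, collapse = ", "))
    o1 <- match(df$founder1, founder_ids); o2 <- match(df$founder2, founder_ids)
  } else {
    all_ids <- sort(unique(c(df$founder1, df$founder2)))
    o1 <- match(df$founder1, all_ids)
    o2 <- match(df$founder2, all_ids)
  }
  swap <- o1 > o2
  tmp <- df$founder1[swap]; df$founder1[swap] <- df$founder2[swap]
  df$founder2[swap] <- tmp
  .new_ibd_segments(df)
}

#' Write IBD segments as tab-separated text
#' @param segments an `ibd_segments` data.frame
#' @param path output file
#' @export
write_ibd_segments <- function(segments, path) {
  write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
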