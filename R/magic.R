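# Forward simulation of the MAGIC crossing scheme: a balanced funnel over
# the founders, several generations of random intercrossing, then doubled
# haploid (DH) induction. A DH line is fully specified by a single gamete,
# so DH induction is modeled as one final meiosis whose product is doubled.

#' Describe a MAGIC crossing scheme
#'
#' @param n_founders number of founders; must be a power of 2 for a
#'   balanced funnel
#' @param n_intercross generations of random intercrossing after the
#'   funnel (default 3)
#' @param intercross_size individuals per intercross cycle (default 1600,
#'   scalable)
#' @param n_dh number of DH lines to extract
#' @param funnel optional permutation of founder indices giving the leaf
#'   order of the funnel tree (consecutive pairs are crossed, then pairs
#'   of pairs, and so on); defaults to a random order drawn when the
#'   scheme is simulated
#' @param allow_selfing may an intercross individual be crossed to itself?
#'   (default FALSE)
#' @return object of class `magic_scheme`
#' @export
magic_scheme <- function(n_founders = 16, n_intercross = 3,
                         intercross_size = 1600, n_dh = 344,
                         funnel = NULL, allow_selfing = FALSE) {
  if (n_founders < 2 || bitwAnd(n_founders, n_founders - 1L) != 0)
    stop_invalid("n_founders must be a power of 2 for a balanced funnel")
  if (intercross_size < 2 && n_intercross > 0)
    stop_invalid("degenerate-scheme: intercross population size must be >= 2")
  if (n_dh < 1) stop_invalid("n_dh must be >= 1")
  if (!is.null(funnel)) {
    if (!setequal(funnel, seq_len(n_founders)))
      stop_invalid("funnel must be a permutation of 1..n_founders")
    funnel <- as.integer(funnel)
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_intercross = as.integer(n_intercross),
                 intercross_size = as.integer(intercross_size),
                 n_dh = as.integer(n_dh),
                 funnel = funnel,
                 allow_selfing = isTRUE(allow_selfing)),
            class = "magic_scheme")
}

#' @export
print.magic_scheme <- function(x, ...) {
  cat("MAGIC scheme:", x$n_founders, "founders ->",
      x$n_intercross, "intercross generations x", x$intercross_size,
      "->", x$n_dh, "DH lines\n")
  invisible(x)
}

# one individual = list(h1, h2) of mosaics
.cross <- function(a, b, map) {
  list(h1 = meiosis(list(a$h1, a$h2), map),
       h2 = meiosis(list(b$h1, b$h2), map))
}

# build one f-way funnel individual from the leaf order
.funnel_individual <- function(leaves, map, founder_gametes) {
  if (length(leaves) == 1L) {
    g <- founder_gametes[[leaves]]
    return(list(h1 = g, h2 = g))
  }
  half <- length(leaves) / 2L
  a <- .funnel_individual(leaves[seq_len(half)], map, founder_gametes)
  b <- .funnel_individual(leaves[-seq_len(half)], map, founder_gametes)
  .cross(a, b, map)
}

#' Simulate a MAGIC DH population
#'
#' Runs the crossing scheme forward: every intercross founder individual is
#' produced by an independent run of the funnel, the synthetic population
#' is randomly mated for `n_intercross` generations (parents drawn
#' uniformly, selfing excluded by default), and DH lines are extracted by
#' one additional meiosis whose doubled gamete is the line's genome.
#'
#' @param founders a `founder_set`
#' @param scheme a `magic_scheme`
#' @param map a `genetic_map` (defaults to the founders' map)
#' @param seed optional RNG seed
#' @return object of class `magic_population`: list with `mosaics` (one
#'   `ancestry_mosaic` per DH line), `map`, `scheme` (with the realized
#'   funnel order) and `founder_ids`
#' @examples
#' map <- simulate_map(1, 50, 100, 1e6, seed = 1)
#' fnd <- simulate_founders(map, f = 4, seed = 2)
#' pop <- simulate_magic(fnd, magic_scheme(4, 1, 20, n_dh = 10), seed = 3)
#' @export
simulate_magic <- function(founders, scheme = magic_scheme(), map = NULL,
                           seed = NULL) {
  set_seed_if(seed)
  map <- map %||% founders$map
  f <- scheme$n_founders
  if (f != n_founders(founders))
    stop_invalid("scheme founder count does not match the founder set")
  funnel <- scheme$funnel %||% sample.int(f)
  founder_gametes <- lapply(seq_len(f), founder_mosaic, map = map)

  size <- max(scheme$intercross_size, if (scheme$n_intercross == 0) scheme$n_dh else 2L)
  pop <- lapply(seq_len(size), function(i)
    .funnel_individual(funnel, map, founder_gametes))

  for (gen in seq_len(scheme$n_intercross)) {
    if (length(pop) < 2L)
      stop_invalid("degenerate-scheme: fewer than 2 individuals during intercross")
    pop <- lapply(seq_len(size), function(i) {
      if (scheme$allow_selfing) {
        pr <- sample.int(length(pop), 2L, replace = TRUE)
      } else {
        pr <- sample.int(length(pop), 2L)
      }
      .cross(pop[[pr[1]]], pop[[pr[2]]], map)
    })
  }

  sel <- if (scheme$n_dh <= length(pop)) sample.int(length(pop), scheme$n_dh)
         else sample.int(length(pop), scheme$n_dh, replace = TRUE)
  mosaics <- lapply(pop[sel], function(ind)
    meiosis(list(ind$h1, ind$h2), map))
  names(mosaics) <- sprintf("L%03d", seq_along(mosaics))
  scheme$funnel <- funnel
  structure(list(mosaics = mosaics, map = map, scheme = scheme,
                 founder_ids = founder_ids(founders)),
            class = "magic_population")
}

#' @export
print.magic_population <- function(x, ...) {
  cat("MAGIC population:", length(x$mosaics), "DH lines,",
      x$scheme$n_founders, "founders\n")
  cat("  mean junctions per line:",
      round(mean(vapply(x$mosaics, crossover_count, 1L)), 1), "\n")
  invisible(x)
}

#' Genome share of each founder per line
#'
#' Fraction of each line's genome (bp-weighted) inherited from each
#' founder; rows sum to 1.
#' @param pop a `magic_population`
#' @return lines x founders matrix of shares
#' @export
founder_shares <- function(pop) {
  f <- pop$scheme$n_founders
  tot <- sum(chrom_lengths(pop$map, "bp"))
  out <- t(vapply(pop$mosaics, function(mos) {
    acc <- numeric(f)
    for (seg in mos) {
      w <- tapply(seg[, 2] - seg[, 1], seg[, 3], sum)
      acc[as.integer(names(w))] <- acc[as.integer(names(w))] + w
    }
    acc / tot
  }, numeric(f)))
  colnames(out) <- pop$founder_ids
  out
}

#' True founder index of every line at every marker
#'
#' @param pop a `magic_population`
#' @param map a `genetic_map` (defaults to the population's map)
#' @return lines x markers integer matrix
#' @export
true_founder_matrix <- function(pop, map = NULL) {
  map <- map %||% pop$map
  out <- matrix(NA_integer_, length(pop$mosaics), nrow(map),
                dimnames = list(names(pop$mosaics), map$marker))
  for (cc in map_chromosomes(map)) {
    idx <- which(map$chrom == cc)
    bp <- map$bp[idx]
    for (i in seq_along(pop$mosaics))
      out[i, idx] <- mosaic_founder_at(pop$mosaics[[i]], cc, bp)
  }
  out
}

#' Pull line genotypes from ancestry mosaics and founder genotypes
#'
#' Each line's allele at a marker is the allele of its founder of origin,
#' optionally flipped at a genotyping-error rate `error`.
#'
#' @param pop a `magic_population`
#' @param founders a `founder_set`
#' @param error per-genotype flip rate (default 0)
#' @return lines x markers 0/1 matrix
#' @export
mosaic_to_genotypes <- function(pop, founders, error = 0) {
  fo <- true_founder_matrix(pop, founders$map)
  n <- nrow(fo); m <- ncol(fo)
  geno <- matrix(founders$geno[cbind(c(fo), rep(seq_len(m), each = n))],
                 n, m, dimnames = dimnames(fo))
  if (error > 0) {
    flip <- matrix(rbinom(length(geno), 1, error) == 1, nrow(geno))
    geno[flip] <- 1 - geno[flip]
  }
  geno
}
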