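# Independent oracles and small fixture builders used across the suite.

# brute-force founder posterior for one line by full path enumeration
enumerate_posterior <- function(obs, founder_geno, cm, error, gens) {
  f <- nrow(founder_geno)
  m <- length(obs)
  stopifnot(f^m <= 1e5)
  r <- 0.5 * (1 - exp(-2 * gens * diff(cm) / 100))
  emis <- function(k, s) {
    if (is.na(obs[k])) return(1)
    if (obs[k] == founder_geno[s, k]) 1 - error else error
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(f)), m)))
  joint <- apply(paths, 1, function(pp) {
    pr <- (1 / f) * emis(1, pp[1])
    for (k in seq_len(m - 1)) {
      tr <- if (pp[k + 1] == pp[k]) 1 - r[k] else r[k] / (f - 1)
      pr <- pr * tr * emis(k + 1, pp[k + 1])
    }
    pr
  })
  post <- matrix(0, m, f)
  for (k in seq_len(m)) for (s in seq_len(f))
    post[k, s] <- sum(joint[paths[, k] == s])
  post / rowSums(post)
}

# union-find membership vector (groups numbered by lowest member)
uf_membership <- function(edges, f) {
  parent <- seq_len(f)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(f), find, 1L)
  match(roots, sort(unique(roots)))
}

# evenly spaced toy map: one or more chromosomes, m markers each
toy_map <- function(n_chrom = 1, m = 10, cm_len = 90, bp_len = 1e6) {
  rows <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    data.frame(chrom = paste0("chr", i),
               marker = sprintf("S%d_%d", i, seq_len(m)),
               bp = round(seq(1, bp_len - 1, length.out = m)),
               cm = seq(0, cm_len, length.out = m))
  }))
  genetic_map(rows,
              chrom_len_bp = setNames(rep(bp_len, n_chrom),
                                      paste0("chr", seq_len(n_chrom))),
              chrom_len_cm = setNames(rep(cm_len, n_chrom),
                                      paste0("chr", seq_len(n_chrom))))
}

# founder set with explicit genotype matrix on a toy map
toy_founders <- function(geno, map) {
  rownames(geno) <- paste0("F", seq_len(nrow(geno)))
  colnames(geno) <- map$marker
  founder_set(geno, map)
}

# small simulated scene reused by several scan tests
sim_scene <- function(seed = 42, f = 4, n_dh = 60, n_chrom = 2, m = 80,
                      cm_len = 80, size = 60) {
  set.seed(seed)
  map <- simulate_map(n_chrom, m, cm_len, 5e7)
  fnd <- simulate_founders(map, f = f, divergence = 0.5)
  pop <- simulate_magic(fnd, magic_scheme(f, 2, size, n_dh = n_dh))
  list(map = map, fnd = fnd, pop = pop,
       geno = mosaic_to_genotypes(pop, fnd))
}

# naive interval-overlap oracle (>= 1 bp), quadratic on purpose
.overlaps_any_test <- function(genes, regions) {
  vapply(seq_len(nrow(genes)), function(i) {
    any(regions$chrom == genes$chrom[i] &
          regions$start < genes$end[i] & regions$end > genes$start[i])
  }, TRUE)
}
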