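# Simulation benchmarks: self-contained validation studies that exercise
# the whole stack (simulator -> inference -> scans) and report the summary
# numbers a study of this design is expected to produce.

#' Founder-assignment accuracy benchmark
#'
#' Simulates MAGIC DH populations with the funnel + intercross + DH scheme
#' on an array-density synthetic genome, reconstructs founder ancestry
#' with the HMM, and scores per-SNP assignment accuracy against the true
#' simulated mosaics.
#'
#' @param n_pops number of simulated populations (default 3)
#' @param n_lines DH lines per population (default 110)
#' @param n_chrom,n_markers,cm_len,bp_len genome layout (defaults: 2
#'   chromosomes x 2,000 markers, 150 cM / 300 Mb each)
#' @param f,divergence founder panel (defaults 16 founders at 0.5 pairwise
#'   divergence)
#' @param error genotyping-error rate used both to corrupt the genotypes
#'   and in the HMM emission model (default 0.002)
#' @param gens HMM map-expansion factor (default 7)
#' @param cycle_size intercross population size per cycle (default 150;
#'   the crossing-scheme design, not the statistic, sets this)
#' @param seed RNG seed
#' @return list with `accuracy_pct` (mean per-SNP accuracy, percent),
#'   `confident_fraction`, and `per_pop` accuracy vector
#' @export
benchmark_founder_assignment <- function(n_pops = 3, n_lines = 110,
                                         n_chrom = 2, n_markers = 2000,
                                         cm_len = 150, bp_len = 3e8,
                                         f = 16, divergence = 0.5,
                                         error = 0.002, gens = 7,
                                         cycle_size = 150, seed = NULL) {
  set_seed_if(seed)
  map <- simulate_map(n_chrom, n_markers, cm_len, bp_len)
  fnd <- simulate_founders(map, f = f, divergence = divergence)
  acc <- conf <- numeric(n_pops)
  for (i in seq_len(n_pops)) {
    pop <- simulate_magic(fnd, magic_scheme(f, 3, cycle_size,
                                            n_dh = n_lines))
    geno <- mosaic_to_genotypes(pop, fnd, error = error)
    post <- infer_founder_probabilities(geno, fnd, error = error,
                                        gens = gens)
    a <- assignment_accuracy(post, pop)
    acc[i] <- a$accuracy
    conf[i] <- a$confident_fraction
  }
  list(accuracy_pct = 100 * mean(acc), per_pop = 100 * acc,
       confident_fraction = mean(conf),
       n = n_pops * n_lines * n_chrom * n_markers)
}

#' Founder genome-share benchmark
#'
#' Mean genome share per founder over replicate balanced-funnel
#' populations; the expectation is 100/f percent for every founder.
#'
#' @inheritParams benchmark_founder_assignment
#' @param n_pops number of populations (default 20)
#' @param n_lines DH lines per population (default 50)
#' @return list with `mean_share_pct` (per founder), `max_abs_dev_pct`,
#'   `se_pct` (per-founder standard error over populations)
#' @export
benchmark_founder_share <- function(n_pops = 20, n_lines = 50, n_chrom = 2,
                                    n_markers = 50, cm_len = 100,
                                    bp_len = 2e8, f = 16, cycle_size = 150,
                                    seed = NULL) {
  set_seed_if(seed)
  map <- simulate_map(n_chrom, n_markers, cm_len, bp_len)
  fnd <- simulate_founders(map, f = f)
  sh <- matrix(NA_real_, n_pops, f)
  for (i in seq_len(n_pops)) {
    pop <- simulate_magic(fnd, magic_scheme(f, 3, cycle_size,
                                            n_dh = n_lines))
    sh[i, ] <- colMeans(founder_shares(pop))
  }
  mean_share <- 100 * colMeans(sh)
  list(mean_share_pct = mean_share,
       max_abs_dev_pct = max(abs(mean_share - 100 / f)),
       se_pct = 100 * apply(sh, 2, sd) / sqrt(n_pops),
       n = n_pops * n_lines)
}

#' Interchromosomal LD null benchmark
#'
#' Under neutral random mating the simulator produces no high LD between
#' chromosomes; counts SNP pairs on different chromosomes with R^2 above
#' the cutoff across replicate populations.
#'
#' @inheritParams benchmark_founder_assignment
#' @param n_pops number of populations (default 5)
#' @param r2_cutoff high-LD bar (default 0.9)
#' @return list with `n_inter_high` (total count, expected 0) and
#'   `n_pairs_checked`
#' @export
benchmark_interchrom_ld <- function(n_pops = 5, n_lines = 120, n_chrom = 2,
                                    n_markers = 400, cm_len = 120,
                                    bp_len = 2e8, f = 8, cycle_size = 120,
                                    r2_cutoff = 0.9, seed = NULL) {
  set_seed_if(seed)
  map <- simulate_map(n_chrom, n_markers, cm_len, bp_len)
  total <- 0L
  pairs <- 0L
  for (i in seq_len(n_pops)) {
    fnd <- simulate_founders(map, f = f)
    pop <- simulate_magic(fnd, magic_scheme(f, 3, cycle_size,
                                            n_dh = n_lines))
    ld <- ld_r2(mosaic_to_genotypes(pop, fnd), map, r2_cutoff = r2_cutoff)
    total <- total + ld$n_inter_high
    pairs <- pairs + ld$n_inter
  }
  list(n_inter_high = total, n_pairs_checked = pairs, n = n_pops * n_lines)
}

#' QTL detection power benchmark (founder model)
#'
#' Replicates a power study for the founder-probability scan: each
#' replicate simulates an 8-parent MAGIC DH population, plants one
#' founder-architecture QTL explaining a fixed fraction of phenotypic
#' variance over a polygenic background (the number of carrier founders
#' cycles over 1..4, varying the causal allele frequency), scans with
#' QTL_F at a genome-wide 5% permutation threshold, and scores a success
#' when a significant peak's support interval covers the causal locus.
#'
#' The founder-probability design uses the simulator's true ancestry,
#' isolating mapping power from ancestry-inference error.
#'
#' @param n_reps number of replicate populations (default 100)
#' @param n_lines DH lines per replicate (default 300)
#' @param f founders (default 8)
#' @param n_chrom,n_markers,cm_len,bp_len genome layout; the default is a
#'   maize-like genome of 10 chromosomes x 150 cM / 200 Mb with 200
#'   markers each (2,000 tested markers), so the genome-wide threshold
#'   carries a realistic multiple-testing burden
#' @param qtl_var phenotypic variance fraction of the planted QTL
#'   (default 0.12)
#' @param h2_poly polygenic heritability (default 0.3)
#' @param n_perm permutations per replicate for the 5% threshold
#'   (default 100)
#' @param grid_step h2 grid resolution for the scans (default 0.05)
#' @param cycle_size intercross population size per cycle (default 300)
#' @param filter_markers apply the R^2 marker filter before scanning?
#'   Default FALSE: the benchmark genome is already within the tested
#'   marker budget, and support intervals keep their natural
#'   ancestry-block width when near-duplicate markers stay in the scan
#' @param seed RNG seed
#' @return list with `power_pct`, `hits` (logical per replicate),
#'   `carriers` (carrier count per replicate)
#' @export
benchmark_qtl_power <- function(n_reps = 100, n_lines = 300, f = 8,
                                n_chrom = 10, n_markers = 200,
                                cm_len = 150, bp_len = 2e8,
                                qtl_var = 0.12, h2_poly = 0.3,
                                n_perm = 100, grid_step = 0.05,
                                cycle_size = 300, filter_markers = FALSE,
                                seed = NULL) {
  set_seed_if(seed)
  hits <- logical(n_reps)
  carriers <- integer(n_reps)
  M <- n_chrom * n_markers
  for (r in seq_len(n_reps)) {
    map <- simulate_map(n_chrom, n_markers, cm_len, bp_len)
    fnd <- simulate_founders(map, f = f)
    pop <- simulate_magic(fnd, magic_scheme(f, 3, cycle_size,
                                            n_dh = n_lines))
    k <- ((r - 1L) %% 4L) + 1L
    carriers[r] <- k
    qbp <- runif(1, 0.1, 0.9) * bp_len
    q <- qtl_spec("chr1", qbp, "founder", var_frac = qtl_var,
                  carriers = sample(f, k))
    ph <- simulate_phenotypes(pop, fnd, qtl = q, h2_poly = h2_poly)
    geno <- mosaic_to_genotypes(pop, fnd)
    truth <- true_founder_matrix(pop)
    post <- array(0, c(n_lines, M, f),
                  dimnames = list(rownames(truth), map$marker,
                                  founder_ids(fnd)))
    post[cbind(rep(seq_len(n_lines), M), rep(seq_len(M), each = n_lines),
               c(truth))] <- 1
    attr(post, "map") <- map
    class(post) <- c("founder_posterior", "array")
    keep <- if (filter_markers) filter_probability_markers(post) else NULL
    mf <- founder_markers(post, keep = keep)
    K <- compute_grm_loco(geno, map)
    th <- permutation_threshold(ph$value, mf, K, n_perm = n_perm,
                                alpha = 0.05, grid_step = grid_step)
    sc <- genome_scan(ph$value, mf, K, grid_step = grid_step)
    if (max(sc$neglog10p, na.rm = TRUE) > th$threshold) {
      si <- support_interval(sc)
      hits[r] <- si$chrom == "chr1" && si$start_bp <= qbp &&
        si$end_bp >= qbp
    }
  }
  list(power_pct = 100 * mean(hits), hits = hits, carriers = carriers,
       n = n_reps)
}
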