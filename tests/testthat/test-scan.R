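# Genome scans under the three allelic models, permutation thresholds,
# support intervals, merging and conditional scans.

# one moderately sized scene shared across blocks in this file
scan_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_scene(seed = 101, f = 8, n_dh = 120, n_chrom = 2, m = 120,
                      cm_len = 90, size = 120)
      sc$post <- infer_founder_probabilities(sc$geno, sc$fnd)
      sc$K <- compute_grm_loco(sc$geno, sc$map)
      cache <<- sc
    }
    cache
  }
})

test_that("QTL_H equals QTL_F marker-for-marker under singleton blocks", {
  sc <- scan_scene()
  empty <- data.frame(founder1 = character(0), founder2 = character(0),
                      chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), start_cm = numeric(0),
                      end_cm = numeric(0))
  blocks <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(empty),
                                   sc$map, paste0("F", 1:8))
  hp <- haplotype_probabilities(sc$post, blocks)
  ph <- simulate_phenotypes(sc$pop, sc$fnd, h2_poly = 0.4, seed = 1)
  y <- ph$value
  mf <- founder_markers(sc$post)
  mh <- haplotype_markers(hp)
  sf <- genome_scan(y, mf, sc$K)
  sh <- genome_scan(y, mh, sc$K)
  expect_equal(sh$lrt, sf$lrt, tolerance = 1e-8)
  expect_equal(sh$p, sf$p, tolerance = 1e-8)
  expect_equal(sf$model[1], "QTL_F")
  expect_equal(sh$model[1], "QTL_H")
})

test_that("a planted founder QTL is recovered at the causal block", {
  sc <- scan_scene()
  q <- qtl_spec("chr1", 2.5e7, "founder", var_frac = 0.35, carriers = c(2, 5))
  ph <- simulate_phenotypes(sc$pop, sc$fnd, qtl = q, h2_poly = 0.2, seed = 2)
  kept <- filter_probability_markers(sc$post)
  mf <- founder_markers(sc$post, keep = kept)
  scan <- genome_scan(ph$value, mf, sc$K)
  peak <- scan[which.max(scan$neglog10p), ]
  expect_equal(peak$chrom, "chr1")
  si <- support_interval(scan)
  expect_true(si$start_bp <= 2.5e7 && si$end_bp >= 2.5e7)
})

test_that("a perfectly tagged bi-allelic variant tops the SNP scan", {
  sc <- scan_scene()
  idx <- which(sc$map$chrom == "chr1")
  tag <- idx[which.min(abs(sc$map$bp[idx] - 2.5e7))]
  q <- qtl_spec("chr1", sc$map$bp[tag], "biallelic", var_frac = 0.4)
  ph <- simulate_phenotypes(sc$pop, sc$fnd, qtl = q, h2_poly = 0.2, seed = 3)
  ms <- snp_markers(sc$geno, sc$map)
  scan <- genome_scan(ph$value, ms, sc$K, grid_step = 0.05)
  top <- scan$marker[which.max(scan$neglog10p)]
  # the top SNP carries the same allele pattern as the causal tag
  expect_gt(cor(sc$geno[, top], sc$geno[, tag])^2, 0.99)
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  sc <- scan_scene()
  ph <- simulate_phenotypes(sc$pop, sc$fnd, h2_poly = 0.3, seed = 4)
  kept <- filter_probability_markers(sc$post)
  mf <- founder_markers(sc$post, keep = kept)
  t1 <- permutation_threshold(ph$value, mf, sc$K, n_perm = 30, seed = 7,
                              grid_step = 0.1)
  t2 <- permutation_threshold(ph$value, mf, sc$K, n_perm = 30, seed = 7,
                              grid_step = 0.1)
  expect_identical(t1$threshold, t2$threshold)
  q01 <- quantile(t1$maxima, 0.99, type = 7)
  q10 <- quantile(t1$maxima, 0.90, type = 7)
  expect_gte(q01, q10)
  expect_error(permutation_threshold(ph$value, mf, sc$K, n_perm = 5), ">= 20")
})

test_that("support intervals follow the 2-drop rule inside a 100-Mb window", {
  map <- toy_map(m = 11, cm_len = 50, bp_len = 2e8)
  prof <- c(1, 2, 5.5, 6, 7.8, 9.9, 8.1, 7.7, 6.2, 5.1, 1)
  scan <- data.frame(marker = map$marker, chrom = map$chrom, bp = map$bp,
                     cm = map$cm, model = "QTL_F", df = 7, lrt = NA,
                     p = 10^(-prof), neglog10p = prof, h2 = 0.5)
  class(scan) <- c("magic_scan", "data.frame")
  si <- support_interval(scan)
  # brute-force oracle over the centered window
  pk <- which.max(prof)
  inwin <- abs(map$bp - map$bp[pk]) <= 50e6
  sel <- inwin & prof >= prof[pk] - 2
  expect_equal(si$start_bp, min(map$bp[sel]))
  expect_equal(si$end_bp, max(map$bp[sel]))
  expect_equal(si$peak_marker, map$marker[pk])

  # plateau of equal values spans all tied markers
  prof2 <- c(1, 1, 6, 6, 6, 6, 6, 1, 1, 1, 1)
  scan2 <- scan; scan2$neglog10p <- prof2; scan2$p <- 10^(-prof2)
  si2 <- support_interval(scan2)
  pk2 <- which.max(prof2)
  sel2 <- abs(map$bp - map$bp[pk2]) <= 50e6 & prof2 >= prof2[pk2] - 2
  expect_equal(si2$start_bp, min(map$bp[sel2]))
  expect_equal(si2$end_bp, max(map$bp[sel2]))
  expect_gte(sum(sel2), 3)  # ties inside the window are all retained

  # only the peak above peak-2: degenerate single-marker interval
  prof3 <- c(1, 1, 1, 1, 9, 1, 1, 1, 1, 1, 1)
  scan3 <- scan; scan3$neglog10p <- prof3; scan3$p <- 10^(-prof3)
  si3 <- support_interval(scan3)
  expect_equal(si3$start_bp, si3$end_bp)
  expect_equal(si3$start_bp, map$bp[5])
})

test_that("QTL merging is transitive with union intervals", {
  rec <- function(ph, chrom, s, e, model, env = "blup", peak = (s + e) / 2,
                  nlp = 6) {
    data.frame(phenotype = ph, environment = env, model = model,
               chrom = chrom, peak_marker = paste0("m", s), peak_bp = peak,
               peak_cm = 1, peak_neglog10p = nlp, start_bp = s, end_bp = e,
               start_cm = 0, end_cm = 2, stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("dta", "chr1", 100, 200, "GWAS_SNP"),
    rec("dta", "chr1", 150, 300, "QTL_F", nlp = 8),
    rec("dta", "chr1", 280, 400, "QTL_H"),   # chains via the middle record
    rec("dta", "chr1", 900, 950, "QTL_F"),   # disjoint
    rec("ph",  "chr1", 100, 200, "QTL_F"),   # different phenotype
    rec("dta", "chr2", 100, 200, "QTL_F"))   # different chromosome
  merged <- merge_qtl(records)
  expect_equal(nrow(merged), 4)
  big <- merged[merged$n_members == 3, ]
  expect_equal(nrow(big), 1)
  expect_equal(big$start_bp, 100)
  expect_equal(big$end_bp, 400)
  expect_equal(big$models, "GWAS_SNP,QTL_F,QTL_H")
  expect_equal(big$best_neglog10p, 8)

  # union-find oracle on pairwise overlaps
  ov <- function(a, b) records$phenotype[a] == records$phenotype[b] &&
    records$chrom[a] == records$chrom[b] &&
    records$start_bp[a] <= records$end_bp[b] &&
    records$end_bp[a] >= records$start_bp[b]
  edges <- which(outer(1:6, 1:6, Vectorize(ov)) & upper.tri(diag(6)),
                 arr.ind = TRUE)
  memb <- uf_membership(edges, 6)
  expect_equal(length(unique(memb)), nrow(merged))
})

test_that("conditioning on the peak removes a single QTL's signal", {
  sc <- scan_scene()
  q <- qtl_spec("chr1", 2.5e7, "founder", var_frac = 0.35, carriers = c(1, 4))
  ph <- simulate_phenotypes(sc$pop, sc$fnd, qtl = q, h2_poly = 0.2, seed = 5)
  kept <- filter_probability_markers(sc$post)
  mf <- founder_markers(sc$post, keep = kept)
  scan <- genome_scan(ph$value, mf, sc$K)
  peak <- scan$marker[which.max(scan$neglog10p)]
  si <- support_interval(scan)
  cond <- conditional_scan(ph$value, mf, sc$K, top_marker = peak,
                           interval = si)
  # the peak itself is collinear with the covariate: skipped
  expect_true(is.na(cond$p[cond$marker == peak]))
  # no residual signal above a lenient bar once the peak is conditioned on
  expect_lt(max(cond$neglog10p, na.rm = TRUE),
            max(scan$neglog10p, na.rm = TRUE) / 2)
})

test_that("two linked QTL: the second peak survives conditioning", {
  sc <- scan_scene()
  q1 <- qtl_spec("chr1", 1.2e7, "founder", var_frac = 0.3, carriers = c(2, 6))
  q2 <- qtl_spec("chr1", 4.2e7, "founder", var_frac = 0.3, carriers = c(3, 7))
  ph <- simulate_phenotypes(sc$pop, sc$fnd, qtl = list(q1, q2),
                            h2_poly = 0.1, seed = 6)
  mf <- founder_markers(sc$post)
  scan <- genome_scan(ph$value, mf, sc$K)
  peak <- scan$marker[which.max(scan$neglog10p)]
  cond <- conditional_scan(ph$value, mf, sc$K, top_marker = peak)
  # the other planted locus still shows strong signal
  other_bp <- if (abs(scan$bp[match(peak, scan$marker)] - 1.2e7) < 1e7)
    4.2e7 else 1.2e7
  near <- abs(cond$bp - other_bp) < 5e6
  expect_gt(max(cond$neglog10p[near], na.rm = TRUE), 3)
})

test_that("background subset scans guard their design and match full scans", {
  sc <- scan_scene()
  ph <- simulate_phenotypes(sc$pop, sc$fnd, h2_poly = 0.3, seed = 8)
  kept <- filter_probability_markers(sc$post)
  mf <- founder_markers(sc$post, keep = kept[1:25])
  full <- genome_scan(ph$value, mf, sc$K, grid_step = 0.05)
  sub <- background_subset_scan(ph$value, mf, sc$K,
                                mask = rep(TRUE, length(ph$value)),
                                grid_step = 0.05)
  expect_equal(sub$p, full$p)
  expect_error(background_subset_scan(ph$value, mf, sc$K, mask = 1:6),
               "too small")
})
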