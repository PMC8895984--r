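# Forward simulator: maps, founders, meiosis, crossing scheme, genotypes.

test_that("simulate_map honors counts, lengths and monotonicity", {
  map <- simulate_map(1, 3, 100, 1e6, seed = 1)
  expect_equal(nrow(map), 3)
  expect_true(all(map$cm >= 0 & map$cm <= 100))
  expect_false(is.unsorted(map$cm))
  expect_false(is.unsorted(map$bp))

  big <- simulate_map(10, 500, 150, 3e8, seed = 2)
  expect_equal(nrow(big), 5000)
  expect_equal(sum(chrom_lengths(big, "cm")), 10 * 150)
  expect_equal(sum(chrom_lengths(big, "bp")), 10 * 3e8)

  expect_error(simulate_map(1, 5, -10, 1e6), "positive")
  expect_error(simulate_map(1, 1, 10, 1e6), "2 markers")
})

test_that("cm/bp interpolation is monotone and mutually consistent", {
  map <- simulate_map(1, 50, 120, 2e7, seed = 3)
  cm <- seq(0, 120, by = 7.5)
  bp <- cm_to_bp(map, "chr1", cm)
  expect_false(is.unsorted(bp))
  back <- bp_to_cm(map, "chr1", bp)
  expect_equal(back, cm, tolerance = 1e-8)
})

test_that("simulate_founders matches the requested divergence", {
  map <- toy_map(m = 4000)
  fnd <- simulate_founders(map, f = 16, divergence = 0.3, seed = 5)
  d <- as.matrix(dist(fnd$geno, method = "manhattan")) / ncol(fnd$geno)
  mean_identity <- mean(1 - d[upper.tri(d)])
  expect_equal(mean_identity, 0.7, tolerance = 0.02)

  # two-founder limit: divergence 1 means every polymorphic marker differs
  f2 <- simulate_founders(map, f = 2, divergence = 1, seed = 6)
  expect_true(all(f2$geno[1, ] != f2$geno[2, ]))

  expect_error(simulate_founders(map, f = 4, divergence = 0.8), "unattainable")
  expect_error(simulate_founders(map, f = 1), "at least 2")
})

test_that("planted IBD tracts force identical alleles and are recorded", {
  map <- toy_map(m = 200, cm_len = 50)
  plan <- data.frame(founder1 = c("F1", "F2"), founder2 = c("F2", "F3"),
                     chrom = "chr1", start_cm = c(10, 12), end_cm = c(15, 20))
  fnd <- simulate_founders(map, f = 4, divergence = 0.4, ibd_plan = plan,
                           seed = 7)
  win <- map$cm >= 10 & map$cm <= 15
  expect_true(all(fnd$geno["F1", win] == fnd$geno["F2", win]))
  # overlap 12-15 is transitively shared by all three
  ov <- map$cm >= 12 & map$cm <= 15
  expect_true(all(fnd$geno["F1", ov] == fnd$geno["F3", ov]))
  expect_equal(nrow(fnd$ibd_truth), 2)

  bad <- data.frame(founder1 = "F1", founder2 = "F1", chrom = "chr1",
                    start_cm = 0, end_cm = 5)
  expect_error(simulate_founders(map, f = 4, ibd_plan = bad), "invalid-plan")
})

test_that("meiosis respects the no-recombination and symmetry limits", {
  map0 <- genetic_map(data.frame(chrom = "chr1", marker = c("a", "b"),
                                 bp = c(10, 20), cm = c(0, 0)),
                      chrom_len_bp = c(chr1 = 100),
                      chrom_len_cm = c(chr1 = 0))
  m1 <- founder_mosaic(1, map0); m2 <- founder_mosaic(2, map0)
  g <- meiosis(list(m1, m2), map0, seed = 1)
  expect_equal(crossover_count(g), 0)
  expect_true(g$chr1[1, 3] %in% c(1, 2))

  map <- toy_map(m = 20, cm_len = 300)
  mid <- founder_mosaic(3, map)
  g2 <- meiosis(list(mid, mid), map, seed = 2)
  expect_identical(unclass(g2), unclass(mid))
})

test_that("crossover counts are Poisson with rate 1 per Morgan", {
  map <- toy_map(m = 30, cm_len = 100)
  m1 <- founder_mosaic(1, map); m2 <- founder_mosaic(2, map)
  set.seed(11)
  counts <- replicate(10000, crossover_count(meiosis(list(m1, m2), map)))
  expect_equal(mean(counts), 1, tolerance = 0.05)
  expect_equal(mean(counts == 0), exp(-1), tolerance = 0.02)
  # junctions can only undercount crossovers (back-to-back switches merge)
  expect_equal(var(counts), 1, tolerance = 0.1)
})

test_that("gamete mosaics tile the chromosome with alternating founders", {
  map <- toy_map(n_chrom = 2, m = 25, cm_len = 150)
  m1 <- founder_mosaic(1, map); m2 <- founder_mosaic(2, map)
  set.seed(12)
  for (i in 1:20) {
    g <- meiosis(list(m1, m2), map)
    for (cc in names(g)) {
      seg <- g[[cc]]
      expect_equal(unname(seg[1, 1]), 0)
      expect_equal(unname(seg[nrow(seg), 2]), chrom_lengths(map, "bp")[[cc]])
      if (nrow(seg) > 1) {
        expect_true(all(seg[-1, 1] == seg[-nrow(seg), 2]))      # no gaps
        expect_true(all(seg[-1, 3] != seg[-nrow(seg), 3]))      # alternates
      }
    }
  }
})

test_that("a 2-founder scheme with no recombination yields pure-founder lines", {
  map0 <- genetic_map(data.frame(chrom = "chr1", marker = c("a", "b"),
                                 bp = c(10, 20), cm = c(0, 0)),
                      chrom_len_bp = c(chr1 = 100),
                      chrom_len_cm = c(chr1 = 0))
  fnd <- toy_founders(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE), map0)
  pop <- simulate_magic(fnd, magic_scheme(2, 0, 2, n_dh = 400), seed = 3)
  shares <- founder_shares(pop)
  expect_true(all(rowSums(shares) == 1))
  expect_true(all(shares %in% c(0, 1)))  # each line wholly one founder
  expect_equal(mean(shares[, 1]), 0.5, tolerance = 0.07)
})

test_that("balanced 16-way funnel gives ~6.25% genome share per founder", {
  map <- toy_map(n_chrom = 1, m = 20, cm_len = 100)
  fnd <- simulate_founders(map, f = 16, seed = 21)
  set.seed(22)
  sh <- colMeans(do.call(rbind, lapply(1:6, function(i) {
    pop <- simulate_magic(fnd, magic_scheme(16, 3, 60, n_dh = 40))
    founder_shares(pop)
  })))
  expect_equal(unname(sh), rep(1 / 16, 16), tolerance = 0.25)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
})

test_that("simulate_magic is reproducible under a fixed seed", {
  map <- toy_map(m = 15, cm_len = 80)
  fnd <- simulate_founders(map, f = 4, seed = 1)
  p1 <- simulate_magic(fnd, magic_scheme(4, 2, 30, n_dh = 12), seed = 99)
  p2 <- simulate_magic(fnd, magic_scheme(4, 2, 30, n_dh = 12), seed = 99)
  expect_identical(p1$mosaics, p2$mosaics)
  expect_identical(vapply(p1$mosaics, crossover_count, 1L),
                   vapply(p2$mosaics, crossover_count, 1L))
})

test_that("mosaic_to_genotypes pulls founder alleles and flips at rate eps", {
  sc <- sim_scene(seed = 31, f = 4, n_dh = 30, m = 100)
  geno <- sc$geno
  expect_true(all(geno %in% c(0, 1)))
  truth <- true_founder_matrix(sc$pop)
  for (i in c(1, 15)) for (j in c(1, 50, 100))
    expect_equal(geno[i, j], unname(sc$fnd$geno[truth[i, j], j]))

  # a single-founder mosaic reproduces that founder's row
  one <- sc$pop
  one$mosaics <- list(L1 = founder_mosaic(2, sc$map))
  g1 <- mosaic_to_genotypes(one, sc$fnd)
  expect_equal(unname(g1[1, ]), unname(sc$fnd$geno[2, ]))

  set.seed(32)
  gerr <- mosaic_to_genotypes(sc$pop, sc$fnd, error = 0.01)
  expect_equal(mean(gerr != geno), 0.01, tolerance = 0.25)
})

test_that("simulate_phenotypes partitions variance as requested", {
  sc <- sim_scene(seed = 41, f = 4, n_dh = 400, m = 60, n_chrom = 2)
  # degenerate: all variance components zero -> constant phenotype
  ph0 <- simulate_phenotypes(sc$pop, sc$fnd, qtl = list(), h2_poly = 0,
                             n_env = 2, n_rep = 2, resid_var = 0, mu = 5,
                             seed = 1)
  expect_true(all(ph0$value == 5))

  # one bi-allelic QTL at 50% variance: regression recovers R2 ~ 0.5
  q <- qtl_spec("chr1", 2.5e7, "biallelic", var_frac = 0.5)
  ph <- simulate_phenotypes(sc$pop, sc$fnd, qtl = q, h2_poly = 0, seed = 2)
  causal <- attr(ph, "truth")$qtl_value
  r2 <- summary(lm(ph$value ~ causal))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.12)

  expect_error(simulate_phenotypes(sc$pop, sc$fnd,
                                   qtl = qtl_spec("chr9", 1, "biallelic", 0.1)),
               "off the map")
  expect_error(simulate_phenotypes(sc$pop, sc$fnd, qtl = list(), h2_poly = 1.2),
               "more than 1|\\[0, 1\\]")
})
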