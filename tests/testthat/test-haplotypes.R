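# Pairwise IBD detection, haplotype block construction, haplotype
# probabilities, stratified filtering, and summaries.

test_that("identical founders yield one chromosome-spanning segment", {
  map <- toy_map(m = 100, cm_len = 50)
  g <- rbind(rbinom(100, 1, 0.5))
  fnd <- toy_founders(rbind(g, g), map)
  seg <- detect_pairwise_ibd(fnd, window_cm = 10, min_len_cm = 0.2)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, map$bp[1])
  expect_equal(seg$end_bp, map$bp[100])

  opp <- toy_founders(rbind(g, 1 - g), map)
  expect_equal(nrow(detect_pairwise_ibd(opp)), 0)
})

test_that("planted tracts are recovered within one marker interval", {
  map <- toy_map(m = 500, cm_len = 100)
  plan <- data.frame(founder1 = "F1", founder2 = "F3", chrom = "chr1",
                     start_cm = 40, end_cm = 45)
  fnd <- simulate_founders(map, f = 4, divergence = 0.5, ibd_plan = plan,
                           seed = 81)
  seg <- detect_pairwise_ibd(fnd, window_cm = 4, min_len_cm = 2)
  hit <- seg[seg$founder1 == "F1" & seg$founder2 == "F3", ]
  expect_equal(nrow(hit), 1)
  # boundaries within one marker spacing (~0.2 cM) of the planted tract
  spacing <- max(diff(map$cm)) * 2
  expect_lt(abs(hit$start_cm - 40), spacing + 1e-9)
  expect_lt(abs(hit$end_cm - 45), spacing + 1e-9)
})

test_that("segment files round-trip and normalize pair orientation", {
  seg <- data.frame(founder1 = c("F2", "F1"), founder2 = c("F1", "F3"),
                    chrom = c("chr1", "chr2"),
                    start_bp = c(100, 5000), end_bp = c(900, 9000),
                    start_cm = c(1.5, 2), end_cm = c(3, 4))
  path <- tempfile(fileext = ".tsv")
  write_ibd_segments(magicqtl:::.new_ibd_segments(seg), path)
  back <- read_ibd_segments(path, founder_ids = c("F1", "F2", "F3"))
  expect_equal(back$founder1, c("F1", "F1"))  # F2-F1 flipped to F1-F2
  expect_equal(back$founder2, c("F2", "F3"))
  expect_equal(back$start_bp, c(100, 5000))
  expect_equal(back$end_cm, c(3, 4))

  # RefinedIBD-style 9-column layout
  rib <- tempfile()
  writeLines(c("F3\t1\tF1\t1\tchr1\t100\t900\t12.3\t0.8",
               "F1\t2\tF2\t1\tchr2\t10\t200\t9.9\t0.4",
               "F2\t1\tF3\t2\tchr2\t50\t400\t3.2\t0.2"), rib)
  got <- read_ibd_segments(rib, founder_ids = c("F1", "F2", "F3"))
  expect_equal(nrow(got), 3)
  expect_equal(got$founder1[1], "F1")
  expect_equal(got$founder2[1], "F3")
  expect_equal(got$end_bp, c(900, 200, 400))

  bad <- tempfile()
  writeLines(c("F1 F2 chr1 100 900", "F1 F2 chr1 oops 900"), bad)
  expect_error(read_ibd_segments(bad), "line 2")
  expect_error(read_ibd_segments(rib, founder_ids = c("F1", "F2")),
               "unknown founder")
})

test_that("no segments means singleton groups in one block per chromosome", {
  map <- toy_map(n_chrom = 2, m = 10, cm_len = 30)
  set.seed(82)
  seg <- detect_pairwise_ibd(toy_founders(matrix(rbinom(80, 1, 0.5), 4, 20),
                                          map))
  empty <- seg[0, ]
  blocks <- build_haplotype_blocks(empty, map, paste0("F", 1:4))
  expect_equal(nrow(blocks$blocks), 2)
  expect_true(all(blocks$blocks$n_hap == 4))
  expect_false(any(blocks$blocks$incomplete))
  expect_equal(unname(blocks$groups[[1]]), 1:4)
})

test_that("incomplete graphs are grouped transitively and flagged", {
  map <- toy_map(m = 10, cm_len = 30, bp_len = 1000)
  seg <- data.frame(founder1 = c("F1", "F1"), founder2 = c("F2", "F3"),
                    chrom = "chr1", start_bp = c(200, 200),
                    end_bp = c(600, 600), start_cm = NA, end_cm = NA)
  blocks <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(seg), map,
                                   paste0("F", 1:4))
  b <- blocks$blocks
  expect_equal(nrow(b), 3)               # [0,200) [200,600) [600,1000)
  mid <- which(b$start_bp == 200)
  expect_equal(b$n_hap[mid], 2)          # {F1,F2,F3} {F4}
  expect_true(b$incomplete[mid])         # F2-F3 edge missing
  expect_equal(unname(blocks$groups[[mid]]), c(1, 1, 1, 2))
  expect_false(any(b$incomplete[-mid]))

  # adding the closing F2-F3 edge removes the flag
  seg2 <- rbind(seg, data.frame(founder1 = "F2", founder2 = "F3",
                                chrom = "chr1", start_bp = 200, end_bp = 600,
                                start_cm = NA, end_cm = NA))
  b2 <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(seg2), map,
                               paste0("F", 1:4))
  expect_false(any(b2$blocks$incomplete))
})

test_that("random segment sets match an interval-sweep + union-find oracle", {
  set.seed(83)
  map <- toy_map(m = 10, cm_len = 30, bp_len = 1000)
  fids <- paste0("F", 1:5)
  for (iter in 1:1000) {
    ns <- sample(0:5, 1)
    if (ns > 0) {
      pr <- t(replicate(ns, sort(sample(5, 2))))
      st <- sample(0:900, ns, replace = TRUE)
      en <- st + sample(50:400, ns, replace = TRUE)
      seg <- data.frame(founder1 = fids[pr[, 1]], founder2 = fids[pr[, 2]],
                        chrom = "chr1", start_bp = st, end_bp = pmin(en, 1000),
                        start_cm = NA, end_cm = NA)
    } else {
      seg <- data.frame(founder1 = character(0), founder2 = character(0),
                        chrom = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), start_cm = numeric(0),
                        end_cm = numeric(0))
    }
    blocks <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(seg), map, fids)
    b <- blocks$blocks
    # oracle: every breakpoint, then union-find on covering segments
    bnd <- sort(unique(c(0, 1000, seg$start_bp, seg$end_bp)))
    bnd <- bnd[bnd >= 0 & bnd <= 1000]
    expect_equal(b$start_bp, bnd[-length(bnd)])
    expect_equal(b$end_bp, bnd[-1])
    for (k in seq_len(nrow(b))) {
      cover <- seg$start_bp <= b$start_bp[k] & seg$end_bp >= b$end_bp[k]
      edges <- cbind(match(seg$founder1[cover], fids),
                     match(seg$founder2[cover], fids))
      expect_equal(unname(blocks$groups[[k]]), uf_membership(edges, 5))
    }
  }
})

test_that("haplotype probabilities sum member founders and conserve mass", {
  sc <- sim_scene(seed = 84, f = 4, n_dh = 12, m = 40)
  post <- infer_founder_probabilities(sc$geno, sc$fnd)
  # single full-genome grouping {F1,F2},{F3},{F4}
  lens <- chrom_lengths(sc$map, "bp")
  seg <- data.frame(founder1 = "F1", founder2 = "F2",
                    chrom = names(lens), start_bp = 0, end_bp = lens,
                    start_cm = NA, end_cm = NA)
  blocks <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(seg), sc$map,
                                   paste0("F", 1:4))
  hp <- haplotype_probabilities(post, blocks)
  expect_equal(hp$prob[[7]][, 1], post[, 7, 1] + post[, 7, 2])
  expect_equal(hp$prob[[7]][, 2], post[, 7, 3])
  sums <- vapply(hp$prob, rowSums, numeric(dim(post)[1]))
  expect_true(all(abs(sums - 1) < 1e-8))

  # all-singleton blocks reproduce the founder posterior exactly
  empty <- seg[0, ]
  sing <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(empty), sc$map,
                                 paste0("F", 1:4))
  hps <- haplotype_probabilities(post, sing)
  for (j in c(1, 20, 40))
    expect_equal(unname(hps$prob[[j]]), unname(matrix(post[, j, ], ncol = 4)))
})

test_that("haplotype filtering never compares across width strata", {
  map <- toy_map(m = 6, cm_len = 10, bp_len = 600)
  n <- 20
  mkmat <- function(h) { m <- matrix(runif(n * h), n); m / rowSums(m) }
  set.seed(85)
  shared <- mkmat(3)
  narrow <- mkmat(2)
  hp <- list(
    prob = list(shared, shared, narrow, narrow, shared, shared),
    markers = data.frame(marker = map$marker, chrom = map$chrom,
                         bp = map$bp, cm = map$cm, block = c(1, 1, 2, 2, 3, 3),
                         n_hap = c(3, 3, 2, 2, 3, 3)))
  class(hp) <- "haplotype_posterior"
  kept <- filter_haplotype_markers(hp, 0.95)
  # duplicates within a stratum drop; stratum changes always retain
  expect_equal(kept, c("S1_1", "S1_3", "S1_5"))
})

test_that("block summaries match hand computation on a small fixture", {
  map <- toy_map(m = 10, cm_len = 20, bp_len = 1000)
  seg <- data.frame(founder1 = c("F1", "F3"), founder2 = c("F2", "F4"),
                    chrom = "chr1", start_bp = c(250, 500),
                    end_bp = c(500, 750), start_cm = NA, end_cm = NA)
  blocks <- build_haplotype_blocks(magicqtl:::.new_ibd_segments(seg), map,
                                   paste0("F", 1:4))
  s <- block_summary(blocks)
  expect_equal(s$genome$n_blocks, 4)
  expect_equal(s$genome$mean_bp, 250)
  expect_equal(s$genome$mean_n_hap, mean(c(4, 3, 3, 4)))
  expect_equal(s$genome$incomplete_fraction, 0)
  expect_equal(s$per_chrom$chrom, "chr1")

  # a single chromosome-spanning block
  one <- build_haplotype_blocks(seg[0, ], map, paste0("F", 1:4))
  s1 <- block_summary(one)
  expect_equal(s1$genome$n_blocks, 1)
  expect_equal(s1$genome$mean_bp, 1000)
  expect_equal(s1$genome$mean_n_hap, 4)
})
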