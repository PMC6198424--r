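test_that("detect_core_regions honours size bounds and the exhaustive rule", {
  # chromosome with 2 SNPs: no cores
  hs2 <- toy_hapset(matrix(0L, 8, 2), pos = c(100, 200))
  expect_equal(nrow(detect_core_regions(hs2, "B1")), 0)
  # constructed set: SNPs 1-5 carry two 50/50 haplotypes; SNP 6 splits
  # each of them below the qualification frequency, breaking coverage
  h1 <- c(0L, 0L, 0L, 0L, 0L)
  h2 <- c(1L, 1L, 1L, 1L, 1L)
  base <- rbind(h1, h1, h1, h1, h1, h2, h2, h2, h2, h2)
  six <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)
  H <- cbind(base, six)
  colnames(H) <- NULL
  hs <- toy_hapset(H, pos = 1:6 * 1000)
  reg <- detect_core_regions(hs, "B1", min_snps = 3, max_snps = 20,
                             hap_freq_min = 0.3, coverage_min = 0.8)
  # exhaustive search oracle over all windows of length 3..6
  qual <- function(cols) {
    key <- apply(H[, cols, drop = FALSE], 1, paste, collapse = "")
    tab <- table(key) / nrow(H)
    sum(tab[tab >= 0.3]) >= 0.8
  }
  best <- 0
  for (L in 6:3) for (s in seq_len(6 - L + 1))
    if (L > best && qual(s:(s + L - 1))) best <- L
  expect_equal(best, 5)   # oracle: the longest qualifying window is 1-5
  expect_equal(reg$first[1], 1)
  expect_equal(reg$last[1], 5)
})

test_that("core regions are pairwise disjoint on random simulations", {
  for (seed in c(41, 42)) {
    cfg <- sim_config(seed = seed, n_breeds = 1, n_per_breed = 25,
                      n_snps = 400, chrom_lengths = rep(2e6, 2), F = 0.1)
    sim <- simulate_dataset(cfg)
    reg <- detect_core_regions(sim$haps, "B1")
    for (ch in unique(reg$chrom)) {
      r <- reg[reg$chrom == ch, ]
      if (nrow(r) > 1)
        expect_true(all(r$first[-1] > r$last[-nrow(r)]))
    }
    expect_true(all(reg$n_snps >= 3 & reg$n_snps <= 20))
  }
})

test_that("enumerate_core_haplotypes counts and symmetry", {
  # 6 chromosomes: strings ACA x3, ACG x2, GCG x1 coded as binary
  H <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L),
             c(0L, 0L, 1L), c(0L, 0L, 1L), c(1L, 0L, 1L))
  hs <- toy_hapset(H, pos = c(100, 200, 300), breed = rep("B1", 3))
  out <- enumerate_core_haplotypes(list(first = 1, last = 3), hs, "B1")
  expect_equal(out$freq, c(3, 2, 1) / 6)
  expect_equal(sum(out$freq), 1)
  # invariant under chromosome reordering
  perm <- c(4, 1, 6, 2, 5, 3)
  hsp <- toy_hapset(H[perm, ], pos = c(100, 200, 300), breed = rep("B1", 3))
  out2 <- enumerate_core_haplotypes(list(first = 1, last = 3), hsp, "B1")
  expect_equal(sort(out2$freq), sort(out$freq))
  # single-founder degeneracy: one haplotype at frequency 1
  cfg <- sim_config(n_breeds = 1, n_per_breed = 8, n_snps = 30,
                    chrom_lengths = 3e5, F = 0.1, n_founders = 1, seed = 43)
  sim <- simulate_dataset(cfg)
  one <- enumerate_core_haplotypes(list(first = 5, last = 9), sim$haps, "B1")
  expect_equal(nrow(one), 1)
  expect_equal(one$freq, 1)
})

test_that("ehh equals the all-pairs brute-force oracle on hand cases", {
  # 4 carriers whose extensions split 2/2 -> EHH = 2/6
  H <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L),
             c(1L, 1L, 1L), c(1L, 1L, 1L))
  hs <- toy_hapset(H, pos = c(10, 500, 1000), breed = rep("B1", 2))
  expect_equal(ehh(hs, 1:4, 1L, 3L), 1 / 3)
  expect_equal(ehh(hs, 1:4, 1L, 3L), oracle_ehh(H, 1:4, 1, 3))
  # target at the core edge -> 1; all identical -> 1; c < 2 -> NA
  expect_equal(ehh(hs, 1:4, 1L, 1L), 1)
  expect_equal(ehh(hs, 1:2, 1L, 3L), 1)
  expect_true(is.na(ehh(hs, 2L, 1L, 3L)))
})

test_that("ehh_bar pools within-haplotype pairs only", {
  # others: (c=4, extensions split 2/2) and (c=2, identical) -> 3/7
  H <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 1L, 0L),
             c(1L, 0L, 1L), c(1L, 0L, 1L))
  hs <- toy_hapset(H, pos = c(10, 600, 1200), breed = rep("B1", 3))
  others <- list(1:4, 5:6)
  expect_equal(ehh_bar(hs, others, 1L, 3L), 3 / 7)
  expect_equal(ehh_bar(hs, others, 1L, 3L), oracle_ehh_bar(H, others, 1, 3))
  # single other haplotype reduces to its own ehh
  expect_equal(ehh_bar(hs, list(1:4), 1L, 3L), ehh(hs, 1:4, 1L, 3L))
  # pooled value lies within [min, max] of the individual EHHs
  e <- c(ehh(hs, 1:4, 1L, 3L), ehh(hs, 5:6, 1L, 3L))
  eb <- ehh_bar(hs, others, 1L, 3L)
  expect_gte(eb, min(e)); expect_lte(eb, max(e))
  # no other haplotype with 2+ carriers -> NA
  expect_true(is.na(ehh_bar(hs, list(3L), 1L, 3L)))
})

test_that("ehh and ehh_bar match the brute-force oracle on random instances", {
  set.seed(44)
  for (i in 1:40) {
    nh <- sample(6:60, 1)
    ns <- sample(8:25, 1)
    H <- matrix(rbinom(nh * ns, 1, runif(1, 0.2, 0.8)), nrow = nh)
    storage.mode(H) <- "integer"
    hs <- toy_hapset(rbind(H, H[seq_len(nh %% 2), , drop = FALSE])[1:nh, ],
                     pos = seq_len(ns) * 100,
                     breed = rep("B1", ceiling(nh / 2)))
    hs$haps <- H
    hs$hap_sample <- rep(seq_len(ceiling(nh / 2)), each = 2)[seq_len(nh)]
    edge <- sample(2:(ns - 1), 1)
    target <- if (runif(1) < 0.5) sample(seq_len(edge - 1), 1) else
      sample((edge + 1):ns, 1)
    rows <- sort(sample(nh, sample(2:min(nh, 12), 1)))
    expect_equal(ehh(hs, rows, edge, target),
                 oracle_ehh(H, rows, edge, target), tolerance = 1e-12)
    grp <- split(seq_len(nh), rbinom(nh, 2, 0.5))
    expect_equal(ehh_bar(hs, grp, edge, target),
                 oracle_ehh_bar(H, grp, edge, target), tolerance = 1e-12)
  }
})

test_that("EHH is non-increasing away from the core", {
  cfg <- sim_config(seed = 45, n_breeds = 1, n_per_breed = 30,
                    n_snps = 200, chrom_lengths = 2e6, F = 0.1)
  sim <- simulate_dataset(cfg)
  reg <- detect_core_regions(sim$haps, "B1")[1, ]
  haps <- enumerate_core_haplotypes(reg, sim$haps, "B1")
  rows <- haps$rows[[1]]
  targets <- (reg$last + 1):min(reg$last + 40, 200)
  vals <- vapply(targets, function(t) ehh(sim$haps, rows, reg$last, t),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("rehh_tests targets, truncation and shared-grouping consistency", {
  cfg <- sim_config(seed = 46, n_breeds = 1, n_per_breed = 20,
                    n_snps = 300, chrom_lengths = 3e6, F = 0.1)
  sim <- simulate_dataset(cfg)
  tests <- rehh_tests(sim$haps, "B1")
  expect_gt(nrow(tests), 0)
  # non-truncated tests sit at >= 1 Mb; truncated ones closer
  expect_true(all(tests$distance_bp[!tests$truncated] >= 1e6))
  expect_true(all(tests$distance_bp[tests$truncated] < 1e6))
  # every reported value equals the literal per-haplotype computation
  for (k in sample(nrow(tests), min(12, nrow(tests)))) {
    tt <- tests[k, ]
    reg <- list(first = tt$core_first, last = tt$core_last)
    haps <- enumerate_core_haplotypes(reg, sim$haps, "B1")
    h <- which(haps$hap == tt$hap)
    edge <- if (tt$direction == "upstream") tt$core_first else tt$core_last
    target <- which(sim$haps$map$pos == tt$target_pos)
    expect_equal(tt$ehh, ehh(sim$haps, haps$rows[[h]], edge, target),
                 tolerance = 1e-12)
    expect_equal(tt$ehh_bar,
                 ehh_bar(sim$haps, haps$rows[-h], edge, target),
                 tolerance = 1e-12)
  }
  # REHH identity: core whose extensions are all identical gives REHH 1
  H <- cbind(matrix(c(0L, 0L, 1L, 1L, 0L, 1L), 6, 3),
             matrix(0L, 6, 5))
  hs <- toy_hapset(H, pos = c(1:3 * 10, 4:8 * 1e5), breed = rep("B1", 3))
  t2 <- rehh_tests(hs, "B1", distance = 1e6,
                   cores = data.frame(chrom = "1", first = 1, last = 3,
                                      n_snps = 3, start = 10, end = 30))
  expect_true(all(t2$rehh == 1))
  expect_true(all(t2$truncated))  # chromosome ends before 1 Mb
})

test_that("rehh_pvalues: normal-tail P, degeneracies, bin bookkeeping", {
  set.seed(47)
  n <- 400
  tests <- data.frame(freq = runif(n, 0.05, 0.95),
                      rehh = exp(rnorm(n, 0, 0.5)))
  pv <- rehh_pvalues(tests, n_bins = 4, min_bin_n = 10)
  t <- pv$tests
  bm <- pv$bin_model
  # a probe whose log REHH equals its bin mean has P = 0.5
  b <- 1
  probe <- data.frame(freq = mean(c(bm$lo[b], bm$hi[b])),
                      rehh = exp(bm$mean[b]))
  allt <- rbind(tests, probe)
  pv2 <- rehh_pvalues(allt, n_bins = 4, min_bin_n = 10)
  expect_equal(pv2$tests$p[n + 1], 0.5, tolerance = 0.05)
  # independent normal-tail oracle for each assessed test
  for (k in sample(which(t$assessed), 20)) {
    z <- (t$log_rehh[k] - bm$mean[t$bin[k]]) / bm$sd[t$bin[k]]
    expect_equal(t$p[k], 1 - pnorm(z), tolerance = 1e-12)
  }
  # all REHH identical in a bin -> sd 0 -> no P
  const <- data.frame(freq = rep(0.5, 30), rehh = rep(2, 30))
  pvc <- rehh_pvalues(const, n_bins = 1, min_bin_n = 10)
  expect_true(all(!pvc$tests$assessed))
  # sparse bin (< min_bin_n) -> no P under equal-width bins
  sparse <- data.frame(freq = c(rep(0.1, 50), rep(0.9, 3)),
                       rehh = exp(rnorm(53)))
  pvs <- rehh_pvalues(sparse, n_bins = 10, min_bin_n = 10,
                      bin_mode = "equal_width")
  expect_true(all(!pvs$tests$assessed[51:53]))
  # non-positive REHH excluded
  bad <- data.frame(freq = rep(0.3, 20), rehh = c(rep(0, 2), exp(rnorm(18))))
  pvb <- rehh_pvalues(bad, n_bins = 1, min_bin_n = 5)
  expect_true(all(!pvb$tests$assessed[1:2]))
})

test_that("select_significant filters by frequency and builds padded regions", {
  tests <- data.frame(breed = "B1", chrom = "1",
                      core_start = c(1e6, 5e6, 9e6),
                      core_end = c(1.2e6, 5.1e6, 9.05e6),
                      freq = c(0.20, 0.25, 0.60),
                      ehh = c(0.9, 0.8, 0.7),
                      rehh = c(9, 8, 7),
                      p = c(1e-5, 5e-4, 0.02),
                      assessed = TRUE)
  sel <- select_significant(tests, freq_min = 0.25, alpha = 0.01,
                            alpha_strong = 0.001, pad = 5e5,
                            chrom_lengths = c("1" = 9.3e6))
  # frequency 0.20 excluded despite tiny P; boundary 0.25 kept
  expect_equal(nrow(sel$kept), 2)
  expect_equal(sel$outliers$freq, 0.25)
  expect_equal(sel$strong$freq, 0.25)
  r <- sel$regions
  expect_equal(r$pad_start, 4.5e6)
  expect_equal(r$pad_end, 5.6e6)
  expect_equal(r$size_kb, (5.1e6 - 5e6) / 1000)
  # clamping at the chromosome end
  tests$p <- 1e-5
  sel2 <- select_significant(tests, chrom_lengths = c("1" = 9.3e6))
  expect_equal(sel2$regions$pad_end[2], 9.3e6)
})

test_that("empirical P fractions behave like the fitted model on synthetic bins", {
  # 1,000 assessed tests drawn from the fitted model give about 10
  # outliers at alpha 0.01 (binomial bounds)
  set.seed(48)
  n <- 1000
  tests <- data.frame(freq = runif(n, 0.3, 0.7),
                      rehh = exp(rnorm(n, -0.2, 0.6)))
  pv <- rehh_pvalues(tests, n_bins = 2, min_bin_n = 10)
  k <- sum(pv$tests$p < 0.01, na.rm = TRUE)
  expect_gte(k, qbinom(0.005, n, 0.01))
  expect_lte(k, qbinom(0.995, n, 0.01))
})
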