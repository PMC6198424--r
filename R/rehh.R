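# Within-breed arm: core-region detection (3-20 consecutive SNPs whose
# common haplotypes cover most chromosomes), extended haplotype
# homozygosity (EHH) and relative EHH (REHH) at ~1 Mb, and frequency-bin
# empirical P-values from a normal fit to log REHH.

# integer group id per row of a binary matrix (identical rows share an
# id); 50-column chunks are bit-packed into doubles and chained
.hap_group_ids <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, ncol = 1)
  n <- nrow(M)
  if (ncol(M) == 0) return(rep(1L, n))
  id <- NULL
  for (st in seq(1, ncol(M), by = 50)) {
    en <- min(st + 49L, ncol(M))
    code <- as.vector(M[, st:en, drop = FALSE] %*% 2^(0:(en - st)))
    key <- if (is.null(id)) code else paste(id, code)
    id <- match(key, unique(key))
  }
  id
}

# group sizes of identical rows of a binary matrix (rows = chromosomes)
.hap_group_sizes <- function(M) {
  id <- .hap_group_ids(M)
  tabulate(id)
}

# pair-homozygosity sum(C(e_g, 2)) over groups
.pair_hom <- function(sizes) sum(choose(sizes, 2))

#' Detect non-overlapping core regions in one breed
#'
#' Greedy left-to-right scan per chromosome: at each anchor SNP the
#' longest window of `min_snps` to `max_snps` consecutive SNPs qualifies
#' as a core region if its haplotypes with frequency at least
#' `hap_freq_min` jointly cover at least `coverage_min` of the breed's
#' chromosomes; after emitting a region the scan resumes past its last
#' SNP, guaranteeing non-overlap.
#'
#' @param hs A `haplotype_set`.
#' @param breed Breed label to scan.
#' @param min_snps,max_snps Core size bounds in SNPs (defaults 3 and 20).
#' @param hap_freq_min Minimum haplotype frequency counted towards
#'   coverage (default 0.05).
#' @param coverage_min Required joint coverage (default 0.8).
#' @return Data frame of core regions: `chrom`, `first`, `last` (global
#'   SNP indices), `n_snps`, `start`, `end` (bp), `span`.
#' @export
detect_core_regions <- function(hs, breed, min_snps = 3L, max_snps = 20L,
                                hap_freq_min = 0.05, coverage_min = 0.8) {
  rows <- .breed_hap_rows(hs, breed)
  if (length(rows) == 0) stop("unknown breed: ", breed)
  H <- hs$haps[rows, , drop = FALSE]
  nh <- nrow(H)
  regions <- list()
  for (ch in unique(hs$map$chrom)) {
    idx <- which(hs$map$chrom == ch)
    n <- length(idx)
    cov_of <- function(ids) {
      s <- tabulate(ids)
      sum(s[s / nh >= hap_freq_min]) / nh
    }
    i <- 1L
    while (i + min_snps - 1L <= n) {
      # coverage is non-increasing in window length (groups only split),
      # so the longest qualifying window is found by growing from the
      # minimum length while coverage holds
      ids <- .hap_group_ids(H[, idx[i:(i + min_snps - 1L)], drop = FALSE])
      hit <- 0L
      if (cov_of(ids) >= coverage_min) {
        hit <- min_snps
        while (hit < max_snps && i + hit <= n) {
          key <- paste(ids, H[, idx[i + hit]])
          ids2 <- match(key, unique(key))
          if (cov_of(ids2) < coverage_min) break
          ids <- ids2
          hit <- hit + 1L
        }
      }
      if (hit > 0L) {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = ch, first = idx[i], last = idx[i + hit - 1L],
                     n_snps = hit, start = hs$map$pos[idx[i]],
                     end = hs$map$pos[idx[i + hit - 1L]],
                     stringsAsFactors = FALSE)
        i <- i + hit
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), first = integer(), last = integer(),
               n_snps = integer(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  out$span <- out$end - out$start
  out
}

#' Enumerate the distinct haplotypes of a core region
#'
#' @param region One row of [detect_core_regions()] output (or any list
#'   with `first` and `last` SNP indices).
#' @param hs A `haplotype_set`.
#' @param breed Breed label.
#' @return Data frame of distinct allele strings with `carriers` (count),
#'   `freq` (summing to 1) and the carrier haplotype rows as a list
#'   column `rows`.
#' @export
enumerate_core_haplotypes <- function(region, hs, breed) {
  rows <- .breed_hap_rows(hs, breed)
  M <- hs$haps[rows, region$first:region$last, drop = FALSE]
  key <- do.call(paste0, as.data.frame(M))
  tab <- sort(table(key), decreasing = TRUE)
  out <- data.frame(hap = names(tab), carriers = as.integer(tab),
                    freq = as.integer(tab) / length(rows),
                    stringsAsFactors = FALSE)
  out$rows <- lapply(out$hap, function(h) rows[key == h])
  out
}

#' Extended haplotype homozygosity of a carrier set
#'
#' Probability that two randomly chosen carrier chromosomes of a core
#' haplotype are identical over the whole interval from the core edge to
#' the target SNP (inclusive; the shared core alleles are excluded).
#' Equals `sum(C(e_g, 2)) / C(c, 2)` over the groups `g` of identical
#' extension strings among the `c` carriers.
#'
#' @param hs A `haplotype_set`.
#' @param carrier_rows Haplotype row indices of the core-haplotype
#'   carriers.
#' @param edge Global SNP index of the core edge on the target's side.
#' @param target Global SNP index of the target SNP (same chromosome).
#' @return EHH in `[0, 1]`; 1 when the target equals the core edge;
#'   `NA` when there are fewer than 2 carriers.
#' @export
ehh <- function(hs, carrier_rows, edge, target) {
  c_t <- length(carrier_rows)
  if (c_t < 2) return(NA_real_)
  if (target == edge) return(1)
  cols <- if (target > edge) (edge + 1L):target else target:(edge - 1L)
  sizes <- .hap_group_sizes(hs$haps[carrier_rows, cols, drop = FALSE])
  .pair_hom(sizes) / choose(c_t, 2)
}

#' Pooled EHH of the other core haplotypes
#'
#' Pools pair counts within each other haplotype (no cross-haplotype
#' pairs): `sum_h sum_g C(e_hg, 2) / sum_h C(c_h, 2)`.
#'
#' @param hs A `haplotype_set`.
#' @param other_rows List of carrier-row vectors, one per other core
#'   haplotype.
#' @inheritParams ehh
#' @return Pooled EHH; `NA` when no other haplotype has 2+ carriers.
#' @export
ehh_bar <- function(hs, other_rows, edge, target) {
  den <- sum(vapply(other_rows, function(r) choose(length(r), 2),
                    numeric(1)))
  if (den == 0) return(NA_real_)
  if (target == edge) return(1)
  cols <- if (target > edge) (edge + 1L):target else target:(edge - 1L)
  num <- sum(vapply(other_rows, function(r) {
    if (length(r) < 2) return(0)
    .pair_hom(.hap_group_sizes(hs$haps[r, cols, drop = FALSE]))
  }, numeric(1)))
  num / den
}

# find the REHH target SNP: first SNP at >= distance bp from the core
# edge in the given direction; falls back to the furthest available SNP
# (truncated = TRUE); NULL when no SNP lies beyond the edge.
.rehh_target <- function(map, chrom_idx, edge, direction, distance) {
  pos <- map$pos
  if (direction == "downstream") {
    beyond <- chrom_idx[chrom_idx > edge]
    if (length(beyond) == 0) return(NULL)
    far <- beyond[pos[beyond] - pos[edge] >= distance]
    if (length(far)) list(target = far[1], truncated = FALSE)
    else list(target = beyond[length(beyond)], truncated = TRUE)
  } else {
    beyond <- chrom_idx[chrom_idx < edge]
    if (length(beyond) == 0) return(NULL)
    far <- beyond[pos[edge] - pos[beyond] >= distance]
    if (length(far)) list(target = far[length(far)], truncated = FALSE)
    else list(target = beyond[1], truncated = TRUE)
  }
}

#' All REHH tests for one breed
#'
#' For every core region and every qualifying core haplotype (frequency
#' at least `test_freq_min`, the same 5% cutoff that lets a haplotype
#' count towards core coverage, and at least two carriers), computes
#' EHH, the pooled EHH of *all* other haplotypes of the region and their
#' ratio REHH at about `distance` bp (default 1 Mb ~ 1 cM) both upstream
#' and downstream; near chromosome ends the furthest available SNP is
#' used and flagged `truncated`. Tests whose pooled-other denominator is
#' empty are skipped.
#'
#' @param hs A `haplotype_set`.
#' @param breed Breed label.
#' @param distance Test distance in bp (default 1e6).
#' @param cores Optional precomputed [detect_core_regions()] output.
#' @param test_freq_min Minimum focal-haplotype frequency for a test
#'   (default 0.05); rarer haplotypes still contribute to the pooled
#'   denominator of the others' EHH.
#' @param ... Passed to [detect_core_regions()].
#' @return Data frame, one row per (core haplotype, direction):
#'   region/core coordinates, `hap`, `freq`, `carriers`, `direction`,
#'   `target_pos`, `distance_bp`, `ehh`, `ehh_bar`, `rehh`, `truncated`.
#' @export
rehh_tests <- function(hs, breed, distance = 1e6, cores = NULL,
                       test_freq_min = 0.05, ...) {
  if (is.null(cores)) cores <- detect_core_regions(hs, breed, ...)
  chrom_idx_all <- split(seq_len(nrow(hs$map)), hs$map$chrom)
  breed_rows <- .breed_hap_rows(hs, breed)
  H <- hs$haps[breed_rows, , drop = FALSE]
  acc <- vector("list", 2L * nrow(cores) * 4L)  # generous upper bound
  n_out <- 0L
  for (r in seq_len(nrow(cores))) {
    reg <- cores[r, ]
    haps <- enumerate_core_haplotypes(reg, hs, breed)
    # carrier rows relative to the breed's haplotype block
    rel <- lapply(haps$rows, function(x) match(x, breed_rows))
    pair_den <- choose(haps$carriers, 2)
    cidx <- chrom_idx_all[[reg$chrom]]
    for (direction in c("upstream", "downstream")) {
      edge <- if (direction == "upstream") reg$first else reg$last
      tg <- .rehh_target(hs$map, cidx, edge, direction, distance)
      if (is.null(tg)) next
      cols <- if (tg$target > edge) (edge + 1L):tg$target else
        tg$target:(edge - 1L)
      # one extension grouping shared by every core haplotype
      ids <- .hap_group_ids(H[, cols, drop = FALSE])
      hom <- vapply(rel, function(x) .pair_hom(tabulate(ids[x])),
                    numeric(1))
      for (h in seq_len(nrow(haps))) {
        if (haps$carriers[h] < 2 || haps$freq[h] < test_freq_min) next
        den_other <- sum(pair_den[-h])
        if (den_other == 0) next
        e <- hom[h] / pair_den[h]
        eb <- sum(hom[-h]) / den_other
        n_out <- n_out + 1L
        acc[[n_out]] <- list(
          breed = breed, chrom = reg$chrom, region = r,
          core_first = reg$first, core_last = reg$last,
          core_start = reg$start, core_end = reg$end,
          hap = haps$hap[h], freq = haps$freq[h],
          carriers = haps$carriers[h], direction = direction,
          target_pos = hs$map$pos[tg$target],
          distance_bp = abs(hs$map$pos[tg$target] - hs$map$pos[edge]),
          ehh = e, ehh_bar = eb,
          rehh = if (eb > 0) e / eb else NA_real_,
          truncated = tg$truncated)
      }
    }
  }
  if (n_out == 0L) return(data.frame())
  acc <- acc[seq_len(n_out)]
  out <- data.frame(
    breed = vapply(acc, `[[`, "", "breed"),
    chrom = vapply(acc, `[[`, "", "chrom"),
    region = vapply(acc, function(x) as.integer(x$region), 0L),
    core_first = vapply(acc, function(x) as.integer(x$core_first), 0L),
    core_last = vapply(acc, function(x) as.integer(x$core_last), 0L),
    core_start = vapply(acc, function(x) as.numeric(x$core_start), 0),
    core_end = vapply(acc, function(x) as.numeric(x$core_end), 0),
    hap = vapply(acc, `[[`, "", "hap"),
    freq = vapply(acc, `[[`, 0, "freq"),
    carriers = vapply(acc, function(x) as.integer(x$carriers), 0L),
    direction = vapply(acc, `[[`, "", "direction"),
    target_pos = vapply(acc, function(x) as.numeric(x$target_pos), 0),
    distance_bp = vapply(acc, function(x) as.numeric(x$distance_bp), 0),
    ehh = vapply(acc, `[[`, 0, "ehh"),
    ehh_bar = vapply(acc, `[[`, 0, "ehh_bar"),
    rehh = vapply(acc, function(x) as.numeric(x$rehh), 0),
    truncated = vapply(acc, `[[`, TRUE, "truncated"),
    stringsAsFactors = FALSE)
  out
}

#' Frequency-bin empirical P-values for REHH tests
#'
#' Haplotypes are allocated to `n_bins` frequency bins; within each bin
#' the mean and sd of `log(REHH)` are fitted and each test's one-sided
#' (upper-tail) normal P is computed. By default bins are equal-count
#' (frequency quantiles), so every bin is fitted on the same number of
#' tests; `bin_mode = "equal_width"` uses fixed-width bins over (0, 1]
#' instead, which is only sensible when the core-haplotype frequency
#' spectrum actually fills the unit interval. Bins with fewer than
#' `min_bin_n` tests or zero sd leave their tests unassessed (`p = NA`).
#' Tests with non-positive or undefined REHH are excluded from the fit
#' and unassessed.
#'
#' @param tests Output of [rehh_tests()].
#' @param n_bins Number of frequency bins (default 20).
#' @param min_bin_n Minimum tests per bin for a fit (default 10).
#' @param bin_mode `"equal_count"` (default) or `"equal_width"`.
#' @return List with `tests` (input plus `bin`, `log_rehh`, `p`,
#'   `assessed`) and `bin_model` (per-bin `n`, frequency bounds `lo`,
#'   `hi`, `mean`, `sd`).
#' @export
rehh_pvalues <- function(tests, n_bins = 20L, min_bin_n = 10L,
                         bin_mode = c("equal_count", "equal_width")) {
  bin_mode <- match.arg(bin_mode)
  if (bin_mode == "equal_width") {
    tests$bin <- pmin(n_bins, pmax(1L, ceiling(tests$freq * n_bins)))
    lo <- (seq_len(n_bins) - 1) / n_bins
    hi <- seq_len(n_bins) / n_bins
  } else {
    br <- unique(stats::quantile(tests$freq, seq(0, 1, length.out = n_bins + 1),
                                 type = 1, names = FALSE))
    if (length(br) < 2) br <- c(0, 1) else {
      br[1] <- 0
      br[length(br)] <- 1
    }
    tests$bin <- cut(tests$freq, br, labels = FALSE)
    lo <- c(br[-length(br)], rep(NA_real_, n_bins + 1 - length(br)))
    hi <- c(br[-1], rep(NA_real_, n_bins + 1 - length(br)))
  }
  ok <- !is.na(tests$rehh) & tests$rehh > 0
  tests$log_rehh <- ifelse(ok, log(tests$rehh), NA_real_)
  bm <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    v <- tests$log_rehh[ok & !is.na(tests$bin) & tests$bin == b]
    data.frame(bin = b, n = length(v),
               lo = lo[b], hi = hi[b],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  tests$p <- NA_real_
  for (b in seq_len(n_bins)) {
    if (bm$n[b] < min_bin_n || is.na(bm$sd[b]) || bm$sd[b] == 0) next
    sel <- ok & !is.na(tests$bin) & tests$bin == b
    tests$p[sel] <- stats::pnorm(tests$log_rehh[sel], mean = bm$mean[b],
                                 sd = bm$sd[b], lower.tail = FALSE)
  }
  tests$assessed <- !is.na(tests$p)
  list(tests = tests, bin_model = bm)
}

#' Select significant core haplotypes and build regions
#'
#' Keeps assessed tests with haplotype frequency at least `freq_min`
#' (the boundary value is kept), flags outliers (`p < alpha`) and strong
#' signals (`p < alpha_strong`), and builds selection regions as the
#' core bp span extended by `pad` on each side, clamped to the
#' chromosome.
#'
#' @param tests Assessed tests (the `tests` element of [rehh_pvalues()]).
#' @param freq_min Haplotype-frequency filter (default 0.25).
#' @param alpha,alpha_strong Significance levels (defaults 0.01, 0.001).
#' @param pad Extension in bp (default 5e5).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clamping the padded end.
#' @return List with `kept` (frequency-filtered assessed tests),
#'   `outliers`, `strong`, and `regions` (one row per strong test:
#'   `breed`, `chrom`, `start`, `end`, `size_kb`, `freq`, `ehh`, `rehh`,
#'   `p`, `pad_start`, `pad_end`).
#' @export
select_significant <- function(tests, freq_min = 0.25, alpha = 0.01,
                               alpha_strong = 0.001, pad = 5e5,
                               chrom_lengths = NULL) {
  kept <- tests[tests$assessed & tests$freq >= freq_min, , drop = FALSE]
  outliers <- kept[kept$p < alpha, , drop = FALSE]
  strong <- kept[kept$p < alpha_strong, , drop = FALSE]
  regions <- data.frame(breed = strong$breed, chrom = strong$chrom,
                        start = strong$core_start, end = strong$core_end,
                        size_kb = (strong$core_end - strong$core_start) / 1000,
                        freq = strong$freq, ehh = strong$ehh,
                        rehh = strong$rehh, p = strong$p,
                        stringsAsFactors = FALSE)
  if (nrow(regions)) {
    cl <- if (is.null(chrom_lengths)) rep(Inf, nrow(regions)) else
      chrom_lengths[as.character(regions$chrom)]
    padded <- pad_region(regions$start, regions$end, pad, cl)
    regions$pad_start <- padded$start
    regions$pad_end <- padded$end
  } else {
    regions$pad_start <- regions$pad_end <- numeric(0)
  }
  list(kept = kept, outliers = outliers, strong = strong,
       regions = regions)
}

#' Full within-breed REHH scan
#'
#' Convenience wrapper: core detection, REHH tests, frequency-bin
#' P-values and significance selection for one or more breeds.
#'
#' @param hs A `haplotype_set`.
#' @param breeds Breed labels (default: all in `hs`).
#' @param distance Test distance in bp (default 1e6).
#' @param test_freq_min Focal-haplotype frequency floor for a test, see
#'   [rehh_tests()].
#' @param n_bins,min_bin_n,bin_mode Binning parameters, see
#'   [rehh_pvalues()].
#' @param freq_min,alpha,alpha_strong,pad See [select_significant()].
#' @param chrom_lengths Optional chromosome lengths for clamping.
#' @param ... Passed to [detect_core_regions()].
#' @return Named list per breed: `cores`, `tests`, `bin_model`,
#'   `selection` (output of [select_significant()]).
#' @export
rehh_scan <- function(hs, breeds = unique(hs$breed), distance = 1e6,
                      test_freq_min = 0.05, n_bins = 20L, min_bin_n = 10L,
                      bin_mode = c("equal_count", "equal_width"),
                      freq_min = 0.25, alpha = 0.01, alpha_strong = 0.001,
                      pad = 5e5, chrom_lengths = NULL, ...) {
  bin_mode <- match.arg(bin_mode)
  out <- lapply(breeds, function(b) {
    cores <- detect_core_regions(hs, b, ...)
    tests <- rehh_tests(hs, b, distance = distance, cores = cores,
                        test_freq_min = test_freq_min)
    if (nrow(tests) == 0)
      return(list(cores = cores, tests = tests, bin_model = NULL,
                  selection = NULL))
    pv <- rehh_pvalues(tests, n_bins = n_bins, min_bin_n = min_bin_n,
                       bin_mode = bin_mode)
    sel <- select_significant(pv$tests, freq_min = freq_min, alpha = alpha,
                              alpha_strong = alpha_strong, pad = pad,
                              chrom_lengths = chrom_lengths)
    list(cores = cores, tests = pv$tests, bin_model = pv$bin_model,
         selection = sel)
  })
  names(out) <- breeds
  out
}
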