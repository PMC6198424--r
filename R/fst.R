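# Diversifying-selection arm: per-SNP pairwise Weir-Cockerham (1984) FST,
# the breed-standardized d_i statistic (sum over pairs of z-scored FST),
# 10-SNP sliding windows and empirical 99.9th-percentile calling.

# Per-SNP summary of one population at every SNP: non-missing sample
# count, counted-allele frequency, observed heterozygote fraction.
.pop_snp_stats <- function(G) {
  n <- colSums(!is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  h <- colMeans(G == 1, na.rm = TRUE)
  list(n = n, p = p, h = h)
}

# Weir-Cockerham (1984) variance components for two populations at every
# SNP. Returns a (among populations), b (among individuals within), c
# (within individuals) and fst = a/(a+b+c); fst is NA where the
# denominator is 0 (both populations monomorphic for the same allele).
.wc_components <- function(s1, s2) {
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)
  a <- nbar / nc *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  denom <- a + b + c
  fst <- ifelse(abs(denom) > 0, a / denom, NA_real_)
  list(a = a, b = b, c = c, denom = denom, fst = fst)
}

#' Per-SNP Weir-Cockerham FST for one breed pair
#'
#' @param g1,g2 Genotype vectors (one SNP; codes 0/1/2, `NA` missing) or
#'   samples x SNPs matrices for the two populations.
#' @return List with per-SNP variance components `a`, `b`, `c`, their sum
#'   `denom`, and `fst` (`NA` where undefined).
#' @export
fst_per_snp <- function(g1, g2) {
  if (!is.matrix(g1)) g1 <- matrix(g1, ncol = 1)
  if (!is.matrix(g2)) g2 <- matrix(g2, ncol = 1)
  .wc_components(.pop_snp_stats(g1), .pop_snp_stats(g2))
}

#' All-pairs per-SNP FST table
#'
#' @param ds A [genotype_dataset()] with at least two breeds.
#' @return Object of class `fst_pair_table`: list with `pairs` (2-column
#'   matrix of breed labels), `fst` (SNPs x pairs matrix, `NA` =
#'   undefined), `a` and `denom` (same shape), `breeds`, and the SNP
#'   `map`.
#' @export
fst_pair_table <- function(ds) {
  breeds <- unique(ds$breed)
  if (length(breeds) < 2) stop("need >= 2 breeds")
  for (b in breeds)
    if (sum(ds$breed == b) < 2) stop("breed with < 2 samples: ", b)
  stats <- lapply(breeds, function(b)
    .pop_snp_stats(ds$G[ds$breed == b, , drop = FALSE]))
  names(stats) <- breeds
  pairs <- t(utils::combn(breeds, 2))
  n_pair <- nrow(pairs)
  fst <- a <- denom <- matrix(NA_real_, nrow = ncol(ds$G), ncol = n_pair)
  for (k in seq_len(n_pair)) {
    w <- .wc_components(stats[[pairs[k, 1]]], stats[[pairs[k, 2]]])
    fst[, k] <- w$fst
    a[, k] <- w$a
    denom[, k] <- w$denom
  }
  colnames(fst) <- colnames(a) <- colnames(denom) <-
    paste(pairs[, 1], pairs[, 2], sep = "-")
  structure(list(pairs = pairs, fst = fst, a = a, denom = denom,
                 breeds = breeds, map = ds$map),
            class = "fst_pair_table")
}

#' Mean and weighted pairwise FST matrices
#'
#' "Mean" is the average of per-SNP FST ratios over defined SNPs
#' (average of ratios); "weighted" is the ratio of summed variance
#' components, `sum(a) / sum(a+b+c)` (ratio of averages).
#'
#' @param x A [fst_pair_table()] or a [genotype_dataset()].
#' @return List of two symmetric matrices `mean` and `weighted` with zero
#'   diagonals.
#' @export
fst_matrix <- function(x) {
  if (inherits(x, "genotype_dataset")) x <- fst_pair_table(x)
  b <- x$breeds
  M <- W <- matrix(0, length(b), length(b), dimnames = list(b, b))
  for (k in seq_len(nrow(x$pairs))) {
    ok <- !is.na(x$fst[, k])
    i <- x$pairs[k, 1]; j <- x$pairs[k, 2]
    M[i, j] <- M[j, i] <- mean(x$fst[ok, k])
    W[i, j] <- W[j, i] <- sum(x$a[ok, k]) / sum(x$denom[ok, k])
  }
  list(mean = M, weighted = W)
}

#' Per-pair FST moments over the panel
#'
#' @param x A [fst_pair_table()].
#' @return Data frame with one row per breed pair: `mean` and `sd`
#'   (sample sd, n-1 denominator) of the per-SNP FST over defined SNPs.
#' @export
pair_moments <- function(x) {
  data.frame(pair = colnames(x$fst),
             breed_i = x$pairs[, 1], breed_j = x$pairs[, 2],
             mean = colMeans(x$fst, na.rm = TRUE),
             sd = apply(x$fst, 2, stats::sd, na.rm = TRUE),
             n_defined = colSums(!is.na(x$fst)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' The breed-standardized d_i statistic
#'
#' Per SNP, the sum over all pairs containing breed `i` of the z-scored
#' pairwise FST, `(FST_ij - E[FST_ij]) / sd[FST_ij]`, with the moments
#' taken over all panel SNPs. SNPs with undefined FST for some pair get a
#' partial sum and a reduced `coverage` count.
#'
#' @param x A [fst_pair_table()].
#' @param breed Breed label `i`.
#' @param moments Optional precomputed [pair_moments()].
#' @return Data frame `snp_id`, `chrom`, `pos`, `di`, `coverage`.
#' @export
di_statistic <- function(x, breed, moments = pair_moments(x)) {
  k <- which(x$pairs[, 1] == breed | x$pairs[, 2] == breed)
  if (length(k) == 0) stop("unknown breed: ", breed)
  if (any(moments$sd[k] == 0 | is.na(moments$sd[k])))
    stop("zero FST sd for pair(s): ",
         paste(moments$pair[k][moments$sd[k] == 0], collapse = ", "))
  z <- sweep(sweep(x$fst[, k, drop = FALSE], 2, moments$mean[k]), 2,
             moments$sd[k], "/")
  data.frame(snp_id = x$map$snp_id, chrom = x$map$chrom, pos = x$map$pos,
             di = rowSums(z, na.rm = TRUE),
             coverage = rowSums(!is.na(z)),
             stringsAsFactors = FALSE)
}

#' Sliding-window means over a per-SNP series
#'
#' Overlapping windows of `window` consecutive SNPs, step one SNP, never
#' crossing a chromosome boundary; a chromosome with fewer SNPs than the
#' window yields no windows.
#'
#' @param values Per-SNP numeric values, aligned with `map`.
#' @param map SNP map (`chrom`, `pos`), sorted.
#' @param window Window size in SNPs (default 10).
#' @return Data frame with one row per window: `chrom`, `first`, `last`
#'   (global SNP indices), `start`, `end` (bp span) and `value` (window
#'   mean).
#' @export
sliding_window_mean <- function(values, map, window = 10L) {
  stopifnot(length(values) == nrow(map))
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    if (n < window) return(NULL)
    cs <- cumsum(c(0, values[idx]))
    first <- seq_len(n - window + 1L)
    data.frame(chrom = ch,
               first = idx[first], last = idx[first + window - 1L],
               start = map$pos[idx[first]],
               end = map$pos[idx[first + window - 1L]],
               value = (cs[first + window] - cs[first]) / window,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), first = integer(),
                      last = integer(), start = integer(), end = integer(),
                      value = numeric(), stringsAsFactors = FALSE)
  out
}

#' Call candidate windows above an empirical percentile
#'
#' The threshold is the smallest window value such that the top
#' `(100 - percentile)%` of windows (by count, ties included) lie at or
#' above it: with `n` distinct values, exactly
#' `floor(n * (1 - percentile/100))` windows are selected.
#'
#' @param windows A data frame from [sliding_window_mean()].
#' @param percentile Empirical percentile (default 99.9).
#' @return The input rows at or above the threshold, with the threshold
#'   attached as attribute `threshold`.
#' @export
call_candidate_windows <- function(windows, percentile = 99.9) {
  n <- nrow(windows)
  if (n == 0) {
    out <- windows
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  if (n < 1000)
    warning("fewer than 1,000 windows; the ", percentile,
            "th percentile is poorly resolved")
  k <- floor(n * (100 - percentile) / 100 + 1e-9)
  v <- sort(windows$value)
  thr <- if (k >= 1) v[n - k + 1L] else v[n]
  if (v[1] == v[n])
    warning("all window values are equal; every window selected")
  out <- windows[windows$value >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Per-breed d_i scan
#'
#' Runs the full diversifying-selection arm for every breed: all-pairs
#' per-SNP FST, d_i, sliding windows and percentile calling.
#'
#' @param ds A (filtered) [genotype_dataset()].
#' @param window Window size in SNPs (default 10).
#' @param percentile Calling percentile (default 99.9).
#' @return List (one element per breed) of lists with `di`, `windows`,
#'   `candidates` and `threshold`; pair table and moments attached as
#'   attributes `pair_table`, `moments`.
#' @export
fst_scan <- function(ds, window = 10L, percentile = 99.9) {
  tab <- fst_pair_table(ds)
  mom <- pair_moments(tab)
  out <- lapply(tab$breeds, function(b) {
    di <- di_statistic(tab, b, mom)
    w <- sliding_window_mean(di$di, tab$map, window)
    cand <- call_candidate_windows(w, percentile)
    list(breed = b, di = di, windows = w, candidates = cand,
         threshold = attr(cand, "threshold"))
  })
  names(out) <- tab$breeds
  attr(out, "pair_table") <- tab
  attr(out, "moments") <- mom
  out
}

#' Two-group pooled FST scan
#'
#' Pools breeds into two super-populations (e.g. white vs spotted coat),
#' computes per-SNP Weir-Cockerham FST between the pools, window means
#' and percentile calling.
#'
#' @param ds A [genotype_dataset()].
#' @param group_a,group_b Disjoint, non-empty breed label vectors.
#' @param window,percentile As in [fst_scan()].
#' @return List with `fst` (per-SNP data frame), `windows`, `candidates`,
#'   `threshold`.
#' @export
group_fst_scan <- function(ds, group_a, group_b, window = 10L,
                           percentile = 99.9) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap: ", paste(intersect(group_a, group_b),
                                   collapse = ", "))
  unknown <- setdiff(c(group_a, group_b), unique(ds$breed))
  if (length(unknown)) stop("unknown breed(s): ",
                            paste(unknown, collapse = ", "))
  Ga <- ds$G[ds$breed %in% group_a, , drop = FALSE]
  Gb <- ds$G[ds$breed %in% group_b, , drop = FALSE]
  w <- fst_per_snp(Ga, Gb)
  per_snp <- data.frame(snp_id = ds$map$snp_id, chrom = ds$map$chrom,
                        pos = ds$map$pos, fst = w$fst,
                        stringsAsFactors = FALSE)
  vals <- ifelse(is.na(w$fst), 0, w$fst)  # undefined SNPs carry no signal
  wins <- sliding_window_mean(vals, ds$map, window)
  cand <- call_candidate_windows(wins, percentile)
  list(fst = per_snp, windows = wins, candidates = cand,
       threshold = attr(cand, "threshold"))
}
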