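# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# Brute-force EHH: enumerate every carrier pair and count identical
# extension strings (core edge exclusive, target inclusive).
oracle_ehh <- function(H, carrier_rows, edge, target) {
  c_t <- length(carrier_rows)
  if (c_t < 2) return(NA_real_)
  if (target == edge) return(1)
  cols <- if (target > edge) (edge + 1):target else target:(edge - 1)
  n_id <- 0
  pairs <- utils::combn(carrier_rows, 2)
  for (k in seq_len(ncol(pairs)))
    if (all(H[pairs[1, k], cols] == H[pairs[2, k], cols]))
      n_id <- n_id + 1
  n_id / ncol(pairs)
}

# Brute-force pooled EHH of "other" haplotypes: within-haplotype pairs
# only.
oracle_ehh_bar <- function(H, other_rows_list, edge, target) {
  num <- 0
  den <- 0
  for (rows in other_rows_list) {
    if (length(rows) < 2) next
    pairs <- utils::combn(rows, 2)
    den <- den + ncol(pairs)
    if (target == edge) {
      num <- num + ncol(pairs)
      next
    }
    cols <- if (target > edge) (edge + 1):target else target:(edge - 1)
    for (k in seq_len(ncol(pairs)))
      if (all(H[pairs[1, k], cols] == H[pairs[2, k], cols]))
        num <- num + 1
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Direct transcription of the two-population Weir-Cockerham (1984)
# component formulas for a single SNP, written scalar-by-scalar.
oracle_wc_fst <- function(g1, g2) {
  count <- function(g) {
    g <- g[!is.na(g)]
    list(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
  }
  x <- count(g1); y <- count(g2)
  r <- 2
  nbar <- (x$n + y$n) / 2
  nc <- (x$n + y$n - (x$n^2 + y$n^2) / (x$n + y$n)) / (r - 1)
  pbar <- (x$n * x$p + y$n * y$p) / (x$n + y$n)
  s2 <- (x$n * (x$p - pbar)^2 + y$n * (y$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (x$n * x$h + y$n * y$h) / (x$n + y$n)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# HWE exact P by full enumeration with raw binomial coefficients
# (choose products), normalized by the marginal C(2n, nA).
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  prob <- vapply(hets, function(h) {
    naa_h <- (2 * n - nA - h) / 2
    nAA_h <- (nA - h) / 2
    exp(lchoose(n, nAA_h) + lchoose(n - nAA_h, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  prob <- prob / sum(prob)  # guard rounding; sums to 1 analytically
  p_obs <- prob[match(nAa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# Monte-Carlo oracle for the realized Weir-Cockerham FST of a
# two-population Balding-Nichols world: replicate the whole generative
# chain (Beta frequencies, binomial genotypes) and average the weighted
# estimator.
oracle_bn_fst <- function(F, n_snps, n_per_pop, p_anc = 0.5, reps = 50,
                          seed = 42) {
  set.seed(seed)
  vals <- replicate(reps, {
    draw <- function() {
      if (F == 0) rep(p_anc, n_snps) else
        stats::rbeta(n_snps, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
    p1 <- draw(); p2 <- draw()
    g1 <- matrix(stats::rbinom(n_per_pop * n_snps, 2, rep(p1, each = n_per_pop)),
                 nrow = n_per_pop)
    g2 <- matrix(stats::rbinom(n_per_pop * n_snps, 2, rep(p2, each = n_per_pop)),
                 nrow = n_per_pop)
    w <- fst_per_snp(g1, g2)
    sum(w$a) / sum(w$denom)
  })
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

# Genotype matrix drawn binomially from a breed x SNP frequency matrix
# (the sampling model of simulate_breed_frequencies' Monte-Carlo oracle).
draw_genotypes_from_freqs <- function(freqs, n_per_breed) {
  do.call(rbind, lapply(seq_len(nrow(freqs)), function(b)
    matrix(stats::rbinom(n_per_breed * ncol(freqs), 2,
                         rep(freqs[b, ], each = n_per_breed)),
           nrow = n_per_breed)))
}

# Small deterministic haplotype_set built directly from a matrix.
toy_hapset <- function(H, pos, chrom = "1", breed = NULL) {
  n_s <- nrow(H) / 2
  if (is.null(breed)) breed <- rep("B1", n_s)
  map <- data.frame(snp_id = paste0("s", seq_along(pos)),
                    chrom = rep(chrom, length.out = length(pos)), pos = pos,
                    stringsAsFactors = FALSE)
  hs <- list(haps = H, map = map,
             samples = paste0("ind", seq_len(n_s)),
             breed = breed,
             hap_sample = rep(seq_len(n_s), each = 2))
  class(hs) <- "haplotype_set"
  hs
}

# Small deterministic genotype_dataset.
toy_dataset <- function(G, pos = seq_len(ncol(G)) * 1000, chrom = "1",
                        breed = rep("B1", nrow(G))) {
  map <- data.frame(snp_id = paste0("s", seq_len(ncol(G))),
                    chrom = rep(chrom, length.out = ncol(G)), pos = pos,
                    stringsAsFactors = FALSE)
  genotype_dataset(G, map, paste0("ind", seq_len(nrow(G))), breed)
}
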