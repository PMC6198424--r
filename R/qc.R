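# SNP quality control: population-wide MAF and missingness filters,
# per-breed exact Hardy-Weinberg tests, and the per-breed polymorphism
# summary.

#' QC configuration
#'
#' @param maf_min Population-wide minor-allele-frequency threshold; SNPs
#'   with MAF strictly below it are removed (default 0.05).
#' @param miss_max Missing-fraction threshold; SNPs with missingness
#'   strictly above it are removed (default 0.20).
#' @param hwe_alpha Per-breed exact-HWE critical P (default 1e-6); a SNP
#'   is removed when P < `hwe_alpha` in any breed (see `hwe_mode`).
#' @param hwe_mode `"any"` (default): remove when failing in any breed;
#'   `"all"`: remove only when failing in every breed.
#' @param maf_poly Per-breed polymorphism cutoff used by
#'   [polymorphism_summary()] (default 0.01).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05, miss_max = 0.20, hwe_alpha = 1e-6,
                      hwe_mode = c("any", "all"), maf_poly = 0.01) {
  hwe_mode <- match.arg(hwe_mode)
  for (v in c(maf_min, miss_max, hwe_alpha, maf_poly))
    if (v < 0 || v > 1) stop("QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, miss_max = miss_max,
                 hwe_alpha = hwe_alpha, hwe_mode = hwe_mode,
                 maf_poly = maf_poly), class = "qc_config")
}

#' Minor allele frequency from 0/1/2 genotype codes
#'
#' @param g Integer vector of genotype codes (0/1/2, `NA` missing) at one
#'   SNP, or a samples x SNPs matrix (column-wise result).
#' @return `min(p, 1-p)` over non-missing alleles; `NA` when all
#'   genotypes are missing.
#' @export
compute_maf <- function(g) {
  if (is.matrix(g)) {
    p <- colMeans(g, na.rm = TRUE) / 2
  } else {
    p <- mean(g, na.rm = TRUE) / 2
  }
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Exact two-sided Hardy-Weinberg test
#'
#' Exact conditional test: given the observed allele counts, the
#' heterozygote count follows a (parity-constrained) hypergeometric-type
#' distribution under HWE; the P-value sums the probabilities of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param nAA,nAa,naa Genotype counts (non-negative, total >= 1).
#' @return Exact P in (0, 1]; degenerate tables (monomorphic) return 1.
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("at least one genotype required")
  nA <- 2L * nAA + nAa
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  if (length(hets) <= 1L) return(1)
  # log P(het = h | nA, n) up to the common normalizer
  logp <- lfactorial(n) -
    lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((2 * n - nA - hets) / 2) + hets * log(2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(nAa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

.genotype_counts <- function(g) {
  c(naa = sum(g == 0, na.rm = TRUE), nAa = sum(g == 1, na.rm = TRUE),
    nAA = sum(g == 2, na.rm = TRUE))
}

#' Apply the SNP filters
#'
#' Filters are applied in order: population-wide MAF, population-wide
#' missingness, then per-breed exact HWE. The report records the count
#' removed at each step (each step sees only the survivors of the
#' previous one).
#'
#' @param ds A [genotype_dataset()].
#' @param config A [qc_config()].
#' @return List with `dataset` (filtered) and `report` (removal counts,
#'   survivor count, per-step survivor tally).
#' @export
filter_snps <- function(ds, config = qc_config()) {
  maf <- compute_maf(ds$G)
  fail_maf <- is.na(maf) | maf < config$maf_min
  keep <- !fail_maf

  miss <- colMeans(is.na(ds$G))
  fail_miss <- keep & miss > config$miss_max
  keep <- keep & !fail_miss

  idx_keep <- which(keep)
  breeds <- unique(ds$breed)
  fail_mat <- matrix(FALSE, nrow = length(breeds), ncol = length(idx_keep))
  for (b in seq_along(breeds)) {
    Gb <- ds$G[ds$breed == breeds[b], idx_keep, drop = FALSE]
    pvals <- vapply(seq_along(idx_keep), function(j) {
      g <- Gb[, j]
      hwe_exact_test(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                     sum(g == 0, na.rm = TRUE))
    }, numeric(1))
    fail_mat[b, ] <- pvals < config$hwe_alpha
  }
  fail_hwe_local <- if (config$hwe_mode == "any") {
    colSums(fail_mat) > 0
  } else {
    colSums(fail_mat) == length(breeds)
  }
  fail_hwe <- logical(ncol(ds$G))
  fail_hwe[idx_keep] <- fail_hwe_local
  keep[fail_hwe] <- FALSE

  report <- list(n_input = ncol(ds$G),
                 removed_maf = sum(fail_maf),
                 removed_missing = sum(fail_miss),
                 removed_hwe = sum(fail_hwe),
                 n_survivors = sum(keep))
  if (report$n_survivors == 0)
    warning("no SNPs survive the QC filters")
  out <- ds
  out$G <- ds$G[, keep, drop = FALSE]
  out$map <- ds$map[keep, , drop = FALSE]
  list(dataset = out, report = report)
}

#' Per-breed polymorphism summary
#'
#' Classifies every panel SNP, per breed, as monomorphic (MAF = 0),
#' low-frequency (0 < MAF <= `maf_poly`) or polymorphic
#' (MAF > `maf_poly`), and reports mean MAF and observed heterozygosity
#' (mean over SNPs of the heterozygous fraction among non-missing
#' genotypes), plus the mean and sd of the inter-marker distance.
#'
#' @param ds A (typically filtered) [genotype_dataset()].
#' @param maf_poly Polymorphism cutoff (default 0.01).
#' @return List with data frame `per_breed` and `spacing`
#'   (`mean_bp`, `sd_bp`).
#' @export
polymorphism_summary <- function(ds, maf_poly = 0.01) {
  breeds <- unique(ds$breed)
  rows <- lapply(breeds, function(b) {
    Gb <- ds$G[ds$breed == b, , drop = FALSE]
    maf <- compute_maf(Gb)
    het <- colMeans(Gb == 1, na.rm = TRUE)
    data.frame(breed = b,
               n_snps = ncol(Gb),
               monomorphic = sum(maf == 0, na.rm = TRUE),
               low_freq = sum(maf > 0 & maf <= maf_poly, na.rm = TRUE),
               polymorphic = sum(maf > maf_poly, na.rm = TRUE),
               mean_maf = mean(maf, na.rm = TRUE),
               obs_het = mean(het, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  gaps <- unlist(lapply(split(ds$map$pos, ds$map$chrom), diff),
                 use.names = FALSE)
  list(per_breed = do.call(rbind, rows),
       spacing = list(mean_bp = mean(gaps), sd_bp = stats::sd(gaps)))
}
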