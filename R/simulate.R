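# Synthetic multi-breed phased-haplotype generator.
#
# The generator stands in for a real multi-breed SNP-array panel: breed
# allele frequencies follow the Balding-Nichols model around a shared
# ancestral frequency, and phased haplotypes are founder mosaics so that
# haplotype homozygosity decays with distance. Hard sweeps can be injected
# as haplotype overwrites with exact ground truth.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic multi-breed
#' generator. Defaults describe a panel small enough for minutes-scale
#' runs but dense enough for 10-SNP windows and ~1 Mb haplotype tests:
#' 5 chromosomes of 20 Mb with 2,000 SNPs each (mean spacing 10 kb) and
#' 4 breeds of 50 diploid samples.
#'
#' @param n_breeds Number of breed-like populations.
#' @param n_per_breed Diploid samples per breed.
#' @param n_snps Total SNP count, split evenly across chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths in bp.
#' @param F Per-breed Balding-Nichols differentiation parameter in `[0, 1)`.
#'   Recycled to `n_breeds`. Defaults chosen so realized mean pairwise FST
#'   spans roughly 0.08-0.17, the range typical of related domestic breeds.
#' @param n_founders Founder haplotypes per breed.
#' @param founder_skew Geometric ratio of the founder contribution
#'   weights (founder k is picked with probability proportional to
#'   `founder_skew^(k-1)`); 1 = equal contributions. The default 0.9
#'   mimics the unequal (popular-sire) founder shares of livestock
#'   breeds and gives common chromosome-scale haplotypes like those seen
#'   on real SNP arrays.
#' @param recomb_rate Crossover density of the founder mosaic, per bp.
#'   The default 3e-7 corresponds to roughly 30 generation-equivalents
#'   of recombination at 1 cM/Mb (1e-8/bp/meiosis) accumulated since the
#'   founder bottleneck, so haplotype homozygosity decays on the
#'   sub-megabase scale typical of livestock SNP-array data.
#' @param missing_rate,error_rate Per-genotype missingness and typing-error
#'   probabilities applied by [degrade_to_genotypes()].
#' @param maf_range Range of the Uniform ancestral-frequency draw; the
#'   default (0.05, 0.95) mimics array ascertainment so most simulated SNPs
#'   survive a 5% MAF filter.
#' @param seed Integer seed making all downstream draws reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_breeds = 4L,
                       n_per_breed = 50L,
                       n_snps = 10000L,
                       chrom_lengths = rep(20e6, 5),
                       F = c(0.05, 0.09, 0.07, 0.15),
                       n_founders = 20L,
                       founder_skew = 0.9,
                       recomb_rate = 3e-7,
                       missing_rate = 0.02,
                       error_rate = 0.001,
                       maf_range = c(0.05, 0.95),
                       seed = 1L) {
  stopifnot(n_breeds >= 1, n_per_breed >= 1, n_snps >= 1,
            all(chrom_lengths > 0), n_founders >= 1, recomb_rate >= 0)
  F <- rep_len(F, n_breeds)
  if (any(F < 0) || any(F >= 1))
    stop("Balding-Nichols F must lie in [0, 1)")
  for (r in c(missing_rate, error_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (founder_skew <= 0 || founder_skew > 1)
    stop("founder_skew must lie in (0, 1]")
  structure(list(n_breeds = as.integer(n_breeds),
                 n_per_breed = as.integer(n_per_breed),
                 n_snps = as.integer(n_snps),
                 chrom_lengths = as.numeric(chrom_lengths),
                 F = F,
                 n_founders = as.integer(n_founders),
                 founder_skew = founder_skew,
                 recomb_rate = recomb_rate,
                 missing_rate = missing_rate,
                 error_rate = error_rate,
                 maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw breed allele frequencies under the Balding-Nichols model
#'
#' Each breed's per-SNP frequency is Beta-distributed with mean equal to
#' the ancestral frequency `p_anc` and variance `F * p * (1 - p)`; `F = 0`
#' degenerates to the ancestral frequencies exactly.
#'
#' @param p_anc Vector of ancestral frequencies, all strictly inside (0, 1).
#' @param F Per-breed differentiation parameter(s) in `[0, 1)`; one row of
#'   the result per element.
#' @return Matrix of dimension `length(F)` x `length(p_anc)`.
#' @export
simulate_breed_frequencies <- function(p_anc, F) {
  if (any(p_anc <= 0) || any(p_anc >= 1))
    stop("ancestral frequencies must be strictly inside (0, 1)")
  if (any(F < 0) || any(F >= 1)) stop("F must lie in [0, 1)")
  out <- matrix(NA_real_, nrow = length(F), ncol = length(p_anc))
  for (b in seq_along(F)) {
    if (F[b] == 0) {
      out[b, ] <- p_anc
    } else {
      scale <- (1 - F[b]) / F[b]
      out[b, ] <- stats::rbeta(length(p_anc),
                               shape1 = p_anc * scale,
                               shape2 = (1 - p_anc) * scale)
    }
  }
  out
}

# Build the SNP map for a config: per chromosome, evenly many SNPs at
# sorted distinct uniform positions.
.sim_snp_map <- function(config) {
  n_chrom <- length(config$chrom_lengths)
  per <- rep(config$n_snps %/% n_chrom, n_chrom)
  extra <- config$n_snps %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  maps <- lapply(seq_len(n_chrom), function(k) {
    pos <- sort(sample.int(config$chrom_lengths[k], per[k]))
    data.frame(chrom = as.character(k), pos = pos,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$snp_id <- sprintf("snp_%s_%d", map$chrom, map$pos)
  map[, c("snp_id", "chrom", "pos")]
}

#' Simulate phased founder-mosaic haplotypes
#'
#' Per breed, `n_founders` founder haplotypes are drawn site-independently
#' from the breed's allele frequencies; each sample haplotype is then a
#' mosaic of founders with crossover breakpoints from a Poisson process at
#' `recomb_rate` per bp. The founder bottleneck is what creates haplotype
#' structure (LD): nearby SNPs tend to descend from the same founder.
#'
#' @param freqs Breed x SNP frequency matrix
#'   (from [simulate_breed_frequencies()]).
#' @param config A [sim_config()].
#' @param map Optional SNP map (`snp_id`, `chrom`, `pos`, sorted); drawn
#'   from the config geometry when omitted.
#' @return A `haplotype_set`: list with binary matrix `haps`
#'   (2 x samples rows), `map`, `samples`, `breed` (per sample), and
#'   `hap_sample` linking haplotype rows to samples.
#' @export
simulate_haplotypes <- function(freqs, config, map = NULL) {
  if (config$n_founders < 1) stop("n_founders must be >= 1")
  if (is.null(map)) map <- .sim_snp_map(config)
  stopifnot(nrow(freqs) == config$n_breeds, ncol(freqs) == nrow(map))
  n_snps <- nrow(map)
  n_hap_breed <- 2L * config$n_per_breed
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chrom_idx) <- chroms

  haps <- matrix(0L, nrow = config$n_breeds * n_hap_breed, ncol = n_snps)
  breed_names <- sprintf("B%d", seq_len(config$n_breeds))
  skew <- if (is.null(config$founder_skew)) 1 else config$founder_skew
  w <- skew^(seq_len(config$n_founders) - 1)
  w <- w / sum(w)
  for (b in seq_len(config$n_breeds)) {
    founders <- matrix(stats::rbinom(config$n_founders * n_snps, 1L,
                                     rep(freqs[b, ], each = config$n_founders)),
                       nrow = config$n_founders, ncol = n_snps)
    row0 <- (b - 1L) * n_hap_breed
    for (h in seq_len(n_hap_breed)) {
      hap <- integer(n_snps)
      for (k in seq_along(chroms)) {
        idx <- chrom_idx[[k]]
        L <- config$chrom_lengths[k]
        n_x <- stats::rpois(1, config$recomb_rate * L)
        if (n_x == 0) {
          hap[idx] <- founders[sample.int(config$n_founders, 1L,
                                          prob = w), idx]
        } else {
          bp <- sort(stats::runif(n_x, 0, L))
          seg <- findInterval(map$pos[idx], bp) + 1L
          fid <- sample.int(config$n_founders, n_x + 1L, replace = TRUE,
                            prob = w)
          pick <- fid[seg]
          for (f in unique(pick))
            hap[idx[pick == f]] <- founders[f, idx[pick == f]]
        }
      }
      haps[row0 + h, ] <- hap
    }
  }
  samples <- sprintf("%s_s%02d", rep(breed_names, each = config$n_per_breed),
                     rep(seq_len(config$n_per_breed), config$n_breeds))
  hs <- list(haps = haps,
             map = map,
             samples = samples,
             breed = rep(breed_names, each = config$n_per_breed),
             hap_sample = rep(seq_along(samples), each = 2L))
  rownames(hs$haps) <- sprintf("%s_h%d", samples[hs$hap_sample],
                               rep(1:2, length(samples)))
  class(hs) <- "haplotype_set"
  hs
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes (%d samples) x %d SNPs, %d chromosome(s), breeds: %s\n",
              nrow(x$haps), length(x$samples), ncol(x$haps),
              length(unique(x$map$chrom)),
              paste(unique(x$breed), collapse = ", ")))
  invisible(x)
}

# haplotype row indices belonging to one breed
.breed_hap_rows <- function(hs, breed) {
  which(hs$breed[hs$hap_sample] == breed)
}

#' Sweep specification
#'
#' Describes one injected hard-sweep-like event: within
#' `[focal_pos - span, focal_pos + span]` on `chrom`, a randomly chosen
#' template haplotype overwrites the interval on a `carrier_fraction`
#' share of the target breed's chromosomes.
#'
#' @param breed Breed label as in the haplotype set.
#' @param chrom Chromosome id.
#' @param focal_pos Focal position in bp.
#' @param span Half-width of the overwritten interval in bp.
#' @param carrier_fraction Target frequency of the swept haplotype, in
#'   `(0, 1]` (0 is accepted as an explicit no-op).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(breed, chrom, focal_pos, span, carrier_fraction) {
  if (carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must lie in [0, 1]")
  structure(list(breed = breed, chrom = as.character(chrom),
                 focal_pos = focal_pos, span = span,
                 carrier_fraction = carrier_fraction),
            class = "sweep_spec")
}

#' Inject a hard-sweep-like haplotype overwrite
#'
#' @param hs A `haplotype_set`.
#' @param spec A [sweep_spec()].
#' @param seed Optional integer seed for the template/carrier draws.
#' @return List with the modified `haplotype_set` (`haps`) and a
#'   `truth` record (spec, affected SNP indices, carrier haplotype rows,
#'   template row).
#' @export
inject_sweep <- function(hs, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(hs$map$chrom == spec$chrom &
                 hs$map$pos >= spec$focal_pos - spec$span &
                 hs$map$pos <= spec$focal_pos + spec$span)
  if (length(idx) == 0) stop("sweep interval contains no SNPs")
  if (!spec$focal_pos >= 1) stop("focal_pos outside chromosome")
  rows <- .breed_hap_rows(hs, spec$breed)
  if (length(rows) == 0) stop("unknown breed: ", spec$breed)
  truth <- list(spec = spec, snp_idx = idx,
                start = min(hs$map$pos[idx]), end = max(hs$map$pos[idx]),
                carriers = integer(0), template = NA_integer_)
  if (spec$carrier_fraction == 0)
    return(list(haps = hs, truth = truth))
  template <- sample(rows, 1L)
  n_carr <- ceiling(spec$carrier_fraction * length(rows))
  carriers <- sample(rows, n_carr)
  hs$haps[carriers, idx] <- matrix(hs$haps[template, idx],
                                   nrow = n_carr, ncol = length(idx),
                                   byrow = TRUE)
  truth$carriers <- carriers
  truth$template <- template
  list(haps = hs, truth = truth)
}

#' Collapse phased haplotypes to noisy unphased genotypes
#'
#' Diploid genotypes are the sums of each sample's two haplotypes; each
#' genotype cell is independently perturbed to a random *other* genotype
#' with probability `error_rate` and set missing with probability
#' `missing_rate` (missingness wins when both fire).
#'
#' @param hs A `haplotype_set`.
#' @param missing_rate,error_rate Probabilities in `[0, 1]`; default to 0.
#' @param seed Optional integer seed.
#' @return A `genotype_dataset` (see [genotype_dataset()]).
#' @export
degrade_to_genotypes <- function(hs, missing_rate = 0, error_rate = 0,
                                 seed = NULL) {
  for (r in c(missing_rate, error_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  odd <- seq(1, nrow(hs$haps), by = 2)
  G <- hs$haps[odd, , drop = FALSE] + hs$haps[odd + 1, , drop = FALSE]
  storage.mode(G) <- "integer"
  n <- length(G)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    if (length(err)) {
      # shift by 1 or 2 (mod 3): always a different genotype
      G[err] <- (G[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    }
  }
  if (missing_rate > 0) G[stats::runif(n) < missing_rate] <- NA_integer_
  rownames(G) <- hs$samples
  genotype_dataset(G, hs$map, hs$samples, hs$breed,
                   coding = "counted allele = simulated '1' allele")
}

#' Simulate a full multi-breed dataset
#'
#' Convenience wrapper: draws ancestral frequencies Uniform over
#' `maf_range`, breed frequencies under Balding-Nichols, founder-mosaic
#' haplotypes, and injects any requested sweeps.
#'
#' @param config A [sim_config()].
#' @param sweeps List of [sweep_spec()] objects (possibly empty).
#' @return List with `haps` (a `haplotype_set`), `freqs`, `p_anc`, and
#'   `truth` (one record per injected sweep).
#' @export
simulate_dataset <- function(config, sweeps = list()) {
  set.seed(config$seed)
  p_anc <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  freqs <- simulate_breed_frequencies(p_anc, config$F)
  hs <- simulate_haplotypes(freqs, config)
  truth <- list()
  for (sp in sweeps) {
    res <- inject_sweep(hs, sp)
    hs <- res$haps
    truth[[length(truth) + 1L]] <- res$truth
  }
  list(haps = hs, freqs = freqs, p_anc = p_anc, truth = truth)
}

#' Write the ground truth of injected sweeps as JSON
#'
#' @param truth List of truth records from [simulate_dataset()] /
#'   [inject_sweep()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  recs <- lapply(truth, function(t)
    list(breed = t$spec$breed, chrom = t$spec$chrom,
         focal_pos = t$spec$focal_pos, span = t$spec$span,
         carrier_fraction = t$spec$carrier_fraction,
         start = t$start, end = t$end, n_snps = length(t$snp_idx)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
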