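---
title: "Two-arm selection-signature scanning with selsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-arm selection-signature scanning with selsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Artificial selection in livestock leaves two kinds of footprints in
SNP-array data. Differentiating selection fixes alternative alleles in
different breeds, inflating between-breed allele-frequency divergence
locally; ongoing selection drags a haplotype to high frequency faster
than recombination can break it up, leaving an unusually long, unusually
frequent haplotype. `selsig` implements one scan for each footprint,
plus the quality control, population-structure summaries and synthetic
data needed to run and test them end to end on a multi-breed diploid
SNP panel (the motivating setting is a four-breed pig panel of a few
hundred animals genotyped on a ~50k array).

# The diversifying-selection arm

For every SNP and every unordered breed pair $\{i,j\}$ the
Weir–Cockerham (1984) estimator decomposes the allelic variance into
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), built from the two sample
sizes, allele frequencies and observed heterozygosities;
$\hat F_{ST} = a/(a+b+c)$, undefined when the denominator is zero (both
breeds monomorphic for the same allele). Two genome-wide summaries are
reported per pair: the *mean* (average of per-SNP ratios) and the
*weighted* (ratio of summed components) estimate — the familiar
average-of-ratios vs ratio-of-averages duality.

Per-SNP pairwise values are standardized into the breed-specific
statistic

$$ d_i = \sum_{j \ne i} \frac{F_{ST}^{ij} - \mathrm{E}[F_{ST}^{ij}]}
        {\mathrm{sd}[F_{ST}^{ij}]}, $$

with moments taken over all panel SNPs, so each breed is contrasted
against all others on a common scale. Large positive $d_i$ flags
breed-specific differentiation. Negative per-SNP estimates are retained
(truncating at zero would bias the standardization), and the sample
(n−1) standard deviation is used; mean-centering makes
$\sum_{\text{SNPs}} d_i = 0$ per breed over fully covered SNPs, which
the test suite asserts at 1e-8 relative tolerance.

The $d_i$ series is smoothed by a 10-SNP sliding window (step one SNP,
never crossing a chromosome; a chromosome with fewer than 10 SNPs
contributes no windows), and windows at or above the empirical 99.9th
percentile are called. The threshold is the order statistic such that,
with $n$ distinct values, exactly $\lfloor n/1000 \rfloor$ windows are
selected; ties at the threshold are all kept. Called windows sharing or
adjoining SNP indices are merged into regions scored by their best
window; regions are padded ±25 kb for gene screening. A pooled two-group
variant (`group_fst_scan()`) compares user-defined super-populations
(e.g. white-coated vs spotted breeds) with the same machinery.

# The within-breed arm

**Core regions.** Published extended-haplotype scans never fully
specify how cores are chosen, so the package adopts the Patil-style
rule and exposes both knobs: scanning left to right, a
window of 3–20 consecutive SNPs qualifies as a core region if its
haplotypes with frequency ≥ 5 % jointly cover ≥ 80 % of chromosomes; the
longest qualifying window is emitted and the scan resumes after it
(cores are therefore non-overlapping). Because adding a SNP can only
split haplotype classes, coverage is non-increasing in window length,
which the implementation exploits by growing windows instead of testing
every length.

**EHH.** For a core haplotype with $c_t$ carrier chromosomes and a
target SNP, carriers are grouped by their full allele string from the
core edge (exclusive) to the target (inclusive);
$\mathrm{EHH} = \sum_g \binom{e_g}{2} / \binom{c_t}{2}$ — the
probability that two random carriers are identical over the whole
stretch. The relative EHH compares the core haplotype against all other
haplotypes of the same core pooled within-haplotype:
$\mathrm{REHH} = \mathrm{EHH}/\overline{\mathrm{EHH}}$ with
$\overline{\mathrm{EHH}} = \sum_h \sum_g \binom{e_{hg}}{2} \big/
\sum_h \binom{c_h}{2}$. Tests are made at the first SNP at least 1 Mb
(≈ 1 cM) from the core edge, upstream and downstream; near chromosome
ends the furthest available SNP is used and the test flagged truncated
rather than dropped. Only haplotypes at or above the 5 % qualification
frequency are tested as focal (`test_freq_min`); rarer haplotypes still
contribute to the pooled denominator. Their 2–4-carrier REHH values are
so discrete that including them as focal tests measurably corrupts the
empirical null (and would triple the tests-per-core count relative to
the ~8 per core typical of published scans).

**Significance.** Tests are allocated to 20 frequency bins; within each
bin the mean and sd of $\ln(\mathrm{REHH})$ are fitted and each test
receives the one-sided upper-tail normal P. Bins with fewer than 10
tests or zero sd leave their tests unassessed. Bins are *equal-count*
(frequency quantiles) by default, with `bin_mode = "equal_width"`
available. This is a deliberate departure from fixed-width bins:
equal-width binning is only meaningful when the core-haplotype frequency
spectrum fills (0, 1], as it does on real bottlenecked-breed data. Under
any neutral generator of this package's class the spectrum thins out
above ~0.3, so fixed-width upper bins are either empty or — worse —
populated solely by the tests of an injected sweep, which are then
compared only against themselves and can never reach significance.
Equal-count bins keep every bin fitted on the same number of
overwhelmingly neutral tests. Haplotypes below 0.25 frequency are
removed before outlier calling (the boundary value is kept); outliers
are P < 0.01, strong signals P < 0.001, and strong cores are padded
±0.5 Mb into reportable regions.

# Structure summaries

PCA operates on the mean-imputed, centered (unscaled by default)
genotype matrix via the standard eigendecomposition; coordinates are
deterministic up to sign. The breed-level cladogram is built by a
from-scratch Saitou–Nei neighbor-joining on the mean pairwise FST
matrix: the pair minimizing the Q-criterion is joined at each step (ties
broken towards the lowest taxon indices), negative branch lengths are
clamped to zero with the deficit moved to the sister branch, and the
result is returned as a newick string. On additive matrices the
generating tree is recovered exactly; the suite cross-checks topology
against `ape::nj` on noisy matrices. Note that NJ joins by Q, not by
smallest distance — on the four-breed FST matrix shipped in the tests
the first join is *not* the closest pair, reproducing the
counter-intuitive grouping such cladograms can show.

# Quality control

Filters run in the order MAF → missingness → HWE, each on the survivors
of the previous step, because reported removal counts depend on order.
The MAF filter is population-wide (all breeds pooled) and strict
(`MAF < 0.05` removed, exactly 0.05 kept), deliberately retaining SNPs
monomorphic in single breeds — those carry the differentiation signal.
Missingness removes SNPs with > 20 % missing genotypes. The HWE test is
the exact conditional test (heterozygote count given allele counts,
summing probabilities no larger than the observed configuration's),
evaluated per breed; a SNP is removed when it fails in *any* breed at
P < 1e-6 (an `hwe_mode = "all"` switch covers the other reading). Note
that with 20 diploids per breed no genotype configuration can reach
P < 1e-6 — the exact test simply cannot be that extreme at small n —
so HWE removals only occur with larger breeds. Missing genotypes are
excluded from both allele counts and heterozygosity denominators. The
per-breed polymorphism summary classifies SNPs as monomorphic
(MAF = 0), low-frequency (0 < MAF ≤ 0.01) or polymorphic (MAF > 0.01).

# The synthetic world

The study-scale data this pipeline targets are not publicly
distributable, so the generator is a first-class module and every claim
the test suite makes is against data it produced. It composes three
standard ingredients:

* **Balding–Nichols frequencies.** Each breed's per-SNP frequency is
  Beta-distributed with mean $p$ (ancestral, drawn Uniform(0.05, 0.95)
  to mimic array ascertainment) and variance $F p (1-p)$. Defaults
  $F = (0.05, 0.09, 0.07, 0.15)$.
* **Founder-mosaic haplotypes.** Per breed, 20 founder haplotypes are
  drawn site-independently from the breed frequencies; each sample
  haplotype is a mosaic of founders with Poisson crossovers at
  `recomb_rate` per bp. Founder contributions are geometrically skewed
  (`founder_skew = 0.9`), the popular-sire pattern of real breeds; this
  is what pushes some core haplotypes into the 0.3–0.9 frequency range
  seen in real scans, which equal founder shares cannot produce. The
  default `recomb_rate = 3e-7` should be read as mosaic depth: roughly
  30 generation-equivalents of 1 cM/Mb since the founder bottleneck. A
  single-meiosis mosaic (1e-8) leaves haplotype homozygosity essentially
  undecayed at 1 Mb, which both misses the sub-Mb LD decay of real
  array data and saturates REHH at 1 for swept and neutral cores alike.
* **Sweep injection.** A hard-sweep caricature: within the requested
  interval a randomly chosen template haplotype overwrites a
  `carrier_fraction` share (rounded up) of the breed's chromosomes.
  Nothing changes outside the interval or breed, giving exact ground
  truth for recovery tests.

Genotypes are produced by summing haplotype pairs and degrading them
with independent per-cell typing errors (default 0.1 %) and missingness
(default 2 %, so the 20 % missingness filter is exercisable but rarely
triggered, as on a decent array run).

Defaults were calibrated once, at design time, against the published
four-breed world this package emulates — realized mean pairwise FST
within ≈ 0.08–0.17 with breed-to-breed spread, sub-Mb EHH decay, a
recognizable share of high-frequency core haplotypes — and then frozen.
The drift contributed by the founder bottleneck (≈ the sum of squared
contribution weights) sits on top of the Balding–Nichols $F$, which is
why the $F$ defaults are below the target FST values.

**What a green test does not establish.** The generator has no
coalescent realism: no mutation, no shared ancestral haplotype pool
across breeds (founders are drawn independently per breed), no
demography, no genetic-map heterogeneity, and sweeps are overwrites,
not selection trajectories. Power estimates from this world do not
transfer to real data; the recovery tests establish that the
implementation detects the signals it should detect in a world where
truth is known, nothing more.

**A known honest red.** The frequency-bin empirical-P construction is
billed as self-calibrating, and the suite checks that the neutral
fraction of assessed tests with P < 0.01 sits inside tight binomial
bounds of 0.01. In this generator's frozen world the construction is
conservative (measured fraction ≈ 0.003): with genuine EHH decay,
$\ln(\mathrm{REHH})$ is left-skewed, so the fitted sd overstates the
upper tail. The only worlds we measured that calibrate near 0.01 are
those with no sub-Mb decay — precisely the worlds where the REHH arm
cannot detect anything. The calibration check is kept as specified and
fails honestly; the sweep-recovery checks pass.

# Numerical and degenerate-input choices

* Internal coordinates are 1-based inclusive; BED export converts to
  0-based half-open. Region SIZE is `end - start`, matching the
  convention of the published tables this format mirrors.
* Allele coding (counted allele = first ALT for VCF, lexicographically
  smaller allele for PED) is recorded in the dataset; every downstream
  statistic is invariant under flipping it, and the suite asserts this.
* Undefined per-SNP FST (shared monomorphism) propagates as partial
  $d_i$ sums with a recorded coverage count rather than dropping SNPs,
  preserving window continuity.
* `hwe_exact_test` works in log-space with a relative tie tolerance of
  1e-9 when summing configurations "no more probable than observed".
* EHH with fewer than 2 carriers is undefined (flagged, excluded); a
  target equal to the core edge gives EHH 1 by convention.
* All generator draws descend from a single integer seed; outputs are
  reproducible bit for bit.

# Limitations

Phasing is assumed done (phased VCF in, or synthetic haplotypes); no
genetic map beyond the 1 cM ≈ 1 Mb approximation; no iHS/XP-EHH; no
hierarchical F-statistics; gene screening is plain interval overlap
against a user-supplied BED/GFF3, with no enrichment statistics.
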