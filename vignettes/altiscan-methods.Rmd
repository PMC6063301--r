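---
title: "Methods: altitude-adaptation scans and demographic inference in altiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: altitude-adaptation scans and demographic inference in altiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`altiscan` targets a specific study design: tens of small, endogamous
populations genotyped on SNP arrays, distributed along a steep altitude
gradient, with two larger external reference populations (an East-Asian-like
close reference and a European-like outgroup). This vignette records the
models, the parameter choices, and the places where the design was genuinely
open — in enough detail that a maintainer can tell deliberate decisions from
accidents.

## Data model and quality control

Genotypes are diploid dosages of `allele_b` (ALT/A2), 0/1/2/`NA`, in a
matrix-backed `genotype_panel`; everything downstream returns tibbles.
Coordinates are 1-based inclusive throughout (VCF/BIM convention) and
chromosome labels are normalized without a `chr` prefix.

`filter_qc()` applies the array-QC cascade in a **fixed order** — variant
call rate ≥ 99%, then sample missingness ≤ 10%, then Hardy–Weinberg exact
p ≥ 1e-7, then an optional MAF floor. The thresholds are the conventional
array values; the ordering is a package decision (any order is defensible,
a fixed one makes removal counts reproducible, and the HWE test is computed
across the samples that survived the missingness step). The HWE test is the
full-enumeration exact test (two-sided, summing probabilities no larger
than the observed heterozygote count's); no mid-p variant, matching the
default behaviour of the standard tooling. Relatedness screening uses
method-of-moments IBD estimation from IBS counts at panel allele
frequencies; `PI_HAT > 0.35` flags a pair and the member with higher
missingness is removed. No small-sample correction is applied to the
expected IBS probabilities, so PI_HAT on panels of only a few samples is
slightly biased upward; the scale of the screening panels (dozens of
samples, thousands of pruned variants) makes this immaterial relative to
the 0.35 threshold. LD pruning is greedy and windowed (50 SNPs, step 5,
r² > 0.5 removes the lower-call-rate member, ties keep the earlier
variant); like the standard implementation it inspects only the sampled
window placements, so a pair just inside the window span but straddling a
step boundary can escape — the invariant tests check the windows actually
scanned.

At panel merge, variants are matched on `(chrom, pos)`; allele
reconciliation resolves REF/ALT swaps (dosage `2 - g`) and strand flips,
and **always** drops A/T and C/G SNPs, which are unresolvable when array
strands differ. This is the conservative standard choice.

## Selection statistics

**Spearman scan.** Per variant, midrank correlation of per-population
derived frequency with altitude, two-sided p from the t-approximation on
n−2 df. The approximation is documented as rough below ~10 populations;
`exact = TRUE` enumerates all rank permutations (feasible to n = 8). With
~20 populations the t-approximation is well within 2× of the exact tail,
which the tests verify at n = 6. Frequencies are unweighted by sample
size: each population is one observation, matching the
population-resolution design of the scan. Variants constant across
populations carry no rank information and are excluded from the test
count, so the Bonferroni denominator is the number of variants actually
tested.

**Mixed model (EMMAX approximation).** The phenotype is each sample's
population altitude in metres (p-values are scale-invariant, so metres
vs kilometres is cosmetic). The null model
`altitude = μ + g + e`, `g ~ N(0, σ²_g K)`, is REML-fitted by 1-D
optimization of the profile likelihood over `log δ`, `δ = σ²_e/σ²_g`, on
the eigenbasis of K (eigenvalues clamped at 0; δ searched over e^±14).
Variance components are then **fixed** and every variant gets a
generalized least-squares Wald test — the defining shortcut of the
approach, orders of magnitude faster than per-SNP REML and the reason a
20,000-variant scan takes seconds. Missing dosages are mean-imputed,
which keeps samples in the eigenbasis; monomorphic or >50%-missing
variants are skipped. K itself is the standardized-genotype covariance
`ZZ′/m` with mean-imputed missing values. With K = cI the GLS collapses
to ordinary least squares exactly, which the tests assert.

**PBS.** Per-SNP Weir–Cockerham FST (1984 two-population estimator with
observed heterozygosity, from genotype counts) for the three group pairs;
negative per-variant estimates are preserved for averaging and clamped to
0 only inside the branch transform, where FST ≥ 1 is clamped to 1−1e−12.
The empirical threshold takes the k-th largest finite PBS,
k = ⌈N(1 − percentile/100)⌉, and flags everything at or above it, so ties
are kept. The focal group H should be a drift-homogeneous pool: pooling
populations with heterogeneous drift inflates within-group heterozygosity
(a Wahlund effect) and deflates the focal FST. This mirrors the original
use of the statistic, where the focal pool is restricted to populations
that cluster together; group membership is therefore a configuration
input, not an automatic choice.

**Evidence combination.** PBS has no parametric null here; it enters the
combination as a rank-p (rank/N, descending, mean-rank ties — the
(rank−0.5)/N variant would avoid p = 1 exactly but rank/N keeps the
maximum-PBS variant at exactly 1/N, and the choice is inconsequential
after −2Σln p). Fisher's χ² = −2Σln p on 6 df combines the three
statistics for variants having all three; the three tests are **not**
independent (they see the same frequencies), so the combined p is a
ranking and flagging device, not a type-1-error rate, and no dependence
correction is applied. Zero p-values are clamped to 1e-300 with a
warning. Candidate regions chain consecutive significant SNPs within
500 kb (single linkage); the gap is a knob — 500 kb reproduces
megabase-scale sweep footprints with internal gaps — and regions below
`min_snps = 2` members are reported but flagged, since singleton hits are
much more often noise.

## Demography

**ROH.** The scan is the PLINK sliding-window algorithm with the window
size left at the PLINK default (50 SNPs; the choice is exposed). A window
is homozygous at ≤ `het_allow` (0) heterozygotes and ≤ `miss_allow` (5)
missing calls; SNPs with ≥ 5% homozygous overlapping windows are
eligible; maximal eligible runs, broken at heterozygous calls, are
reported at ≥ 100 SNPs and ≤ 5 missing calls, with bp bounds at member
SNP positions (not padded window edges — the unpadded choice is
deliberate and documented because the alternative is equally defensible).
Input should be LD-pruned, MAF > 0.05 data (`prefilter = TRUE` does both
internally). Inbreeding F uses the homozygote-excess estimator with the
small-sample factor `2n/(2n−1)` on expected heterozygosity; without it F
is biased by about −1/(2n), which is visible even at hundreds of samples.

**Ne from LD.** Intra-chromosomal pairs are binned by map distance
(Morgans); each pair contributes `y = r² − 1/n`, `n` = 2×samples, the
standard chromosome-sample-size adjustment. The hyperbolic model
`y = 1/(α + βc)` is fitted to bin means by Levenberg–Marquardt (with an
L-BFGS-B fallback for near-collinear gradients), started from the exact
linearization `1/y = α + βc`. Under the drift expectation
`E[y] = 1/(α + 4Ne c)`, long-term `Ne = β/4`; α is estimated freely. The
per-bin trajectory `Ne(t) = (1/y − α̂)/(4c)` at `t = 1/(2c)` generations
is summarized by the harmonic mean over bins with positive estimates, and
years use 29-year generations. Populations need ≥ 10 samples — the
harmonic mean is fragile below that. The β estimate carries only
`~2·c_max` relative signal over the fitted range, so short maps give very
noisy Ne: the package's own validation uses chromosome spans of ~0.09
Morgans and averages replicate panels.

**Divergence times.** The clean-split pure-drift relation
`t = −2·Ne·ln(1 − FST)` generations (`≈ 2·Ne·FST` for small FST). The
method is named after its assumption: migration after the split inflates
shared LD and biases t downward, so the output is labelled approximate.

**f-statistics.** Frequency-based (not pseudo-haploid) estimators, since
inputs are diploid panels. Admixture f3 subtracts the target's
sampling-noise bias `c(1−c)/(2n_c − 1)`; outgroup f3 applies no
correction (the outgroup is held fixed). D uses
`Σ(w−x)(y−z) / Σ(w+x−2wx)(y+z−2yz)`. Standard errors come from the
weighted delete-one block jackknife (Busing et al. 1999 pseudovalues)
over contiguous 500-SNP blocks, the last block short; ratio statistics
jackknife the ratio via delete-one numerator/denominator sums.
Conventional significance: f3 admixture at Z ≤ −3, D at |Z| ≥ 4.
Population filters mirror common practice: ≥ 6 samples for f3/D. The
Mantel test permutes rows and columns jointly, two-sided with the
+1-correction; when n! fits within the permutation budget the enumeration
is exact (and then needs no seed).

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: 20 populations of
10–20 samples, altitudes uniform on 100–4,500 m, Balding–Nichols drift
F ∈ [0.01, 0.2], 20,000 variants on 20 chromosomes (2–4 kb spacing,
1 cM/Mb), 0.5% of loci altitude-selected with slope 0.15 per km planted
in runs of 5 adjacent SNPs (a sweep-like footprint; isolated significant
SNPs would be discarded by the region filter), plus `EAS` (F = 0.02) and
`EUR` (F = 0.16) references of 30 samples at low altitude. Selection is
planted at the population-frequency level — frequencies shifted by
`s × altitude` and clamped to [0.01, 0.99], genotypes redrawn — because
the scan statistics only see frequencies; fitness trajectories would add
nothing the tests could detect. Planted loci draw their ancestral derived
frequency from [0.05, 0.3]: an adaptive derived allele is modelled as
ancestrally rare, which also keeps the planted frequency-altitude
relation monotone instead of saturating at the clamp.

The mosaic haplotype simulator gives each haplotype a Markov founder path
(switch probability per interval = map distance in Morgans; founder
redraw uniform, so the effective change rate is `(1−1/K)` per Morgan).
A founder pool of K haplotypes behaves like a population of K/2 diploids:
`E[r²] ≈ e^{−2c(1−1/K)}/(K−1)`, so the fitted hyperbola recovers
`Ne ≈ K/2` — with substantial founder-realization noise, which is why
validation averages replicates.

Deliberately absent: coalescent/forward simulation, archaic introgression
tracts, SNP-array ascertainment bias, genotyping error, and recombination
hotspots (the constant map is enough for methods that need distances
only). Passing tests on these panels therefore show the statistics do
what they claim under their own model assumptions — drift, admixture,
autozygosity, LD — not that real array data meets those assumptions.

## Problem sizes and seeds

Everything stochastic takes an explicit seed and is bit-reproducible.
The validation suite uses panels of 200–20,000 variants and up to ~340
samples: full-profile scans (20,000 variants) for calibration and
recovery, 100 replicate frequency simulations for the D-statistic
false-positive rate, four replicate mosaic panels (150 samples, 3,000
SNPs) for Ne recovery. These sizes were chosen so the whole suite runs in
a few minutes while leaving the Monte-Carlo error comfortably inside the
asserted tolerances.

## Known limitations

- The LMM phenotype is constant within populations, so its effective
  sample size is closer to the number of populations than of samples;
  p_lmm and p_spearman are strongly dependent, and the Fisher combination
  inherits that (by design, uncorrected).
- W&C FST on a pooled focal group treats the pool as one population;
  heterogeneous pools deflate PBS (see above).
- `estimate_pi_hat` assumes panel allele frequencies estimated from the
  data including the pair itself; on very small panels PI_HAT is
  upward-biased.
- The Ne trajectory inherits the equilibrium assumptions of the
  hyperbolic decay model; `t = 1/(2c)` is an order-of-magnitude time
  scale, not a calibrated clock, and divergence times assume no
  post-split migration.
- VCF support is GT-only and biallelic-SNP-only; dosage likelihoods,
  phasing and imputation are out of scope.
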