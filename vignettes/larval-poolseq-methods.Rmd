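---
title: "Methods: pool-seq selection scans for larval cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq selection scans for larval cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascan)
```

# The problem

Broadcast-spawning bivalves produce enormous larval cohorts that suffer
type-III survivorship: 80–98% of fertilized embryos die before settlement.
When a full-factorial (NC-II) cross is reared in replicate tanks and the
pooled DNA of each cohort is sequenced on a schedule of phenotyping days
(0, 11, 16 and 23, with the day-23 survivors sieved into Big and Small
fractions), the time series of pooled allele frequencies carries information
about which markers are associated with survival ("viability-associated
SNPs"), which with growth ("size-associated SNPs"), and whether the overall
regime looks like directional selection, drift, or balancing selection.

`larvascan` implements that analysis end to end — filtering, allele-frequency
calculus, four chi-square scan procedures, consistent-trend selection, a
Monte-Carlo drift null, and summary tables — plus a generative simulator with
known ground truth, so every stage is testable without any external data.

# Data model

The central object is a long count table with one row per marker × sample.
A sample is keyed `Fx.Mx.Rx.Dx[Big|Small]`: female and male parent,
replicate tank, day, and (on day 23 only) sieve fraction. Day-0 pools are
taken from the fertilized population *before* the replicate split, so they
carry no replicate id and are shared by all replicates of a family.
Parental genotypes (from a VCF or the simulator) declare which markers are
*informative*: the parents are homozygous for opposite alleles, so every F1
larva is heterozygous and the reference/alternative reads track the
maternal/paternal haplotypes.

# Filtering

Three filters run in a fixed order, all inclusive at their boundaries:

1. **Parental depth (≥ 40×)** — markers whose parent calls are supported by
   fewer than 40 reads (or no recorded depth) are dropped;
2. **Zero-recovery masking** — an allele count of zero at one time point
   followed by a nonzero count at a later day is biologically impossible
   (an allele absent from a closed cohort cannot reappear), so the whole
   marker × sample cell is converted to missing. Terminal zeros stand. A
   day-0 zero is masked if the allele reappears in *any* replicate, since
   the day-0 pool precedes the split;
3. **Heterozygous set (≥ 20× per allele)** — a marker enters a replicate's
   analysis set when its parents are opposite homozygotes and both alleles
   have at least 20 reads at every nonmissing time point of that replicate's
   series. Masked cells and absent samples are exempt, so a replicate
   missing one day is still analysable.

The size of the retained set is `nHet`, the denominator of every adjusted
significance threshold. Masking before depth-filtering retains a superset of
markers relative to the reverse order; the package tests pin this property.

# Allele-frequency calculus

Pooled frequencies are read-count ratios: `ref_af = r.rc / s.arc` and
`alt_af = a.rc / s.arc`, where `s.arc` is the summed reference and
alternative depth of the cell. Trajectories are *normalized to day 0* as
differences, `delta_af(day) = alt_af(day) − alt_af(day 0)`, which keeps
deltas in [−1, 1] and is invariant to a constant shift of the trajectory
(a ratio normalization is not, and is deliberately not offered as a
default). Per-marker heterozygosity is `ref_af × alt_af` ∈ [0, 0.25], and
"sequence divergence" at day 23 is the sign of the alternative-allele
change, a shift toward the paternal haplotype counting as an increase.

# The scan procedures

All four procedures are Pearson chi-square tests of 2×2 contingency tables
(no continuity correction by default, since the uncorrected Pearson form is
the one whose closed form `n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` the tests use
as an oracle; a `yates` flag enables the correction everywhere). Tables
with a zero margin are undefined and skipped with a log entry; expected
cells below 5 are logged but do not suppress the test.

* **Viability scan** (`viability_scan`): per marker, reference/alternative
  reads at day 0 versus day 23Big, and versus day 23Small when that group
  exists. The threshold is `α = 0.05/nHet` per replicate — a
  heterozygous-marker Bonferroni-style rule. A marker is viability-associated
  only if *every* available test passes; a replicate without a Small group
  is decided by the Big test alone.
* **Haplotype scan** (`haplotype_scan`): the same tables re-oriented to
  female/male haplotype reads (the statistic is invariant to orientation),
  with per-replicate × comparison q-value control at `q < 0.05` instead of
  the `0.05/nHet` rule.
* **Contig scan** (`contig_scan`): haplotype reads are summed over every
  informative marker of a contig; the contig statistic equals the marker
  statistic applied to the summed table. Two analyses run per replicate —
  day 0 vs day 23 (Big and Small both required when both exist) and day 16
  vs day 23Big — each under q < 0.05, and the reported set is their
  intersection.
* **Size scan** (`size_scan`): day-23 Big versus Small reads per marker at
  `p < 0.05/nHet`.

q-values use Benjamini–Hochberg by default; `fdr = "storey"` additionally
estimates the null proportion π₀ on the standard λ grid (0.05–0.95, step
0.05) with a df = 3 smoothing spline, falling back to π₀ = 1 below 100
p-values, where the smoother is unstable.

# Consistent trends and the chance-of-drift null

From the markers of selected contigs, `consistent_trend_markers()` keeps
those whose change is *uniform in direction at each of the four time
points*: the day-0-normalized deltas at day 11, day 16, day 23Big and day
23Small must all share one strict sign (ties break consistency; three
deltas when Small is absent). Under an exchangeable sampling-noise null the
four signs are independent fair coins, so a neutral marker is consistent
with probability `2·(1/2)⁴ = 0.125` — the anchor that fixes this reading.
An alternative `method = "chain"` instead requires the successive steps
D0→D11→D16→{Big, Small} to share a sign (a strictly monotone trajectory);
its neutral probability is far smaller (~1/30) and it is provided for
sensitivity analysis, not as the default.

`chance_of_drift()` makes the null concrete per marker: alternative counts
at each post-day-0 time point are drawn independently as
Binomial(depth_t, p₀) with the day-0 frequency held fixed as the reference,
and the chance of drift is the fraction of simulated trajectories that are
direction-consistent. At p₀ = 0.5 and deep coverage it converges to 0.125
(0.25 with three comparisons); finite depth can only lower it, because ties
fail consistency. The published origin of this statistic is a supplementary
procedure that is not public, so this implementation is a reconstruction
anchored to those limits. Per-replicate chances multiply under independence
(`joint_drift_probability`).

One caveat the null inherits from its fixed-reference construction: in real
data the *observed* day-0 frequency is shared by all four deltas, which
positively correlates their signs and inflates the empirical consistent
fraction when day-0 coverage is comparable to later coverage (in the
extreme of equal noise, up to 2/5). The package's consistency check of
"neutral fraction ≈ chance of drift" therefore uses a much deeper day-0
pool; users comparing the two on real data should keep the asymmetry in
mind.

# The synthetic-data generator

`simulate_pool_study()` emulates the statistical structure of the design:

* **Cross**: `n_females × n_males` families, each with `n_replicates`
  cohorts of `start_cohort_size` fertilized embryos (default 4 × 2 × 3 ×
  120,000). Every marker is informative, the female carrying the reference
  allele. The methods and results of the source design give 4 females × 2
  males; the cross dimensions are a config switch.
* **Segregating planted loci**: at an informative marker all F1 are
  heterozygous, so the within-family pooled frequency is pinned at 1/2 and
  *no* within-cohort selection can move it. Observable frequency shifts
  require residual segregating variation at selected sites (parental
  heterozygosity, miscalls, or linked variants). The generator makes this
  explicit: neutral markers stay all-heterozygous, while planted viability
  and size loci carry dosages drawn from Binomial(2, start frequency).
* **Selection**: survival is multiplicative across loci and per-allele-copy
  within a locus (`w = Π (1+s)^x`), the form under which the expected
  one-locus recursion is exactly the genic `p' = p(1+s)/(1+ps)`; a negative
  direction uses per-copy fitness `1/(1+s)`. Per-stage probabilities are
  rescaled so the expected survivor count matches the stage's survival
  fraction. Three regimes: `directional` (constant s, direction alternating
  across contigs), `fluctuating` (s flips sign between stages; its
  signature is a damped net change, which the tests verify), and
  `balancing` (heterozygote advantage, start frequency 0.2). With many
  jointly selected loci the rescaled probabilities saturate at 1 and
  selection behaves like truncation, so realized per-locus shifts fall
  below the one-locus recursion — a real constraint of viability selection,
  not an artifact, and the reason recovery experiments state their realized
  shifts.
* **Why overdominance for the balancing signature**: a sign-alternating
  walk from an off-centre start is phase-sensitive (a +−+ phase raises
  heterozygosity, a −+− phase lowers it more), so it does not systematically
  reproduce the empirical signature of rising heterozygosity between day 0
  and day 23. Heterozygote advantage — a canonical balancing mechanism —
  does: it drives frequencies toward 1/2 from any start, so day-23
  heterozygosity of selected loci rises while directional selection erodes
  it. The package's balancing regime is therefore overdominant, with
  sign-fluctuating selection available separately.
* **Size split**: each day-23 survivor receives a liability — the sum of
  per-locus effects times dosage plus standard Gaussian noise — and the top
  `1 − sieve_quantile` are labelled Big. At a median split the expected
  Big–Small frequency gap of a planted locus is
  `β·var(x)/σ_L · 2φ(0)`, with `var(x) = 0.5` and `σ_L` the liability SD;
  the default effect 0.55 yields a gap near 0.2 when one or two loci are
  planted. Because the *total* between-fraction divergence is bounded by
  the sieve, many simultaneous size loci necessarily shrink each locus's
  gap (ceiling ≈ 0.13 at 20 loci) — the reason the bundled recovery
  experiment plants two.
* **Pooled reads**: two-stage noise — `pool_sample_size` individuals are
  sampled into the pool (the study's pools were far smaller than the
  cohorts, tens to ~10⁴), then per-marker depth is negative-binomial around
  `mean_depth` (Poisson at zero dispersion) and alternative reads are
  binomial at the pool frequency.
* **Phenotypes and trade-off**: replicate-level lognormal survival jitter
  and a configurable negative coupling between a tank's survival and its
  mean day-23 size generate the phenotype table used by
  `survival_size_correlation()` (explicit, logged outlier exclusion only —
  never automatic).

Everything is reproducible: one seed in the config determines the counts,
the truth tables and the phenotypes byte-for-byte.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: reference-mapping bias, linkage
disequilibrium beyond shared contig membership, overdispersion of allele
counts beyond binomial pooling (e.g. unequal DNA contributions per larva),
contamination of day-0 pools by unfertilized eggs, genotyping error in the
parents, and families segregating at "informative" markers. The scans are
exactly as good as their sampling model on such features.

# Reporting

`build_summary()` assembles one row per replicate — nHet, per-comparison
significant counts, viability SNPs with their percentage of nHet (3
decimals), trend counts split by direction (2 decimals), size SNPs (2
decimals), per-day mean heterozygosity of the viability SNPs and the day-23
divergence split. Percentages round half away from zero at the printed
precision, and every percentage is re-derived from its own numerator and
denominator columns before the table is returned; a mismatch is an error.
Published tables of this kind do contain cells that fail exactly this audit
(a printed percentage irreproducible from its own row), which is why the
audit exists and why the package always reports the formula-consistent
value.

# Numerical choices

* Depth thresholds are inclusive (≥ 40×, ≥ 20×); boundary tests pin both.
* Ties: zero deltas break trend consistency (conservative); divergence ties
  are reported in their own column, never forced into a class.
* Rounding is half-up (`0.125 → 0.13`), not banker's.
* The q-value family is replicate × comparison; Storey π₀ falls back to BH
  below 100 p-values.
* Chi-square tables with a zero margin error out at the single-test level
  and are skipped with a count inside scans; integer cells are promoted to
  double before the products to avoid 32-bit overflow.
* Degenerate inputs: empty cohorts warn and return empty size groups;
  p₀ ∈ {0, 1} gives a chance of drift of exactly 0 with a warning.

# Problem sizes used by the bundled checks

The packaged tests and the acceptance script size their simulations as: 20
neutral replicates × 2,000 markers at depth 100 for type-I control; 2,000
markers (10 per contig) with 20 planted viability loci at depth 200, stage
s = (0.6, 0.3, 1.0) under a late-heavy schedule (0.6, 0.55, 0.12 — overall
4% survival, the metamorphosis-mortality pattern) for recovery, realized
day-0→23 shifts ≈ 0.17; 2 planted size loci (effect 0.6, realized gap ≈
0.21) at depth 300; 300 markers × 50 seeds per regime at depth 600 for the
heterozygosity signature; and 10⁵ Monte-Carlo trajectories for the drift
anchor. At these sizes the whole suite runs in a few minutes on one CPU.

# Known limitations

* The size-scan power at a true gap of 0.2 and 300× pools under the
  `0.05/nHet` threshold is analytically capped near 0.75–0.9 per locus
  (noncentrality ≈ 24 against a critical value ≈ 17.8 at nHet = 2,000), so
  per-locus recovery above 95% is not attainable under those conditions;
  the acceptance suite states the 95% expectation and documents the
  shortfall rather than relaxing it.
* The drift null treats day 0 as noiseless (see the caveat above).
* Contig aggregation assumes within-contig markers share haplotype phase
  through their parents; no linkage-phase inference is attempted beyond the
  per-marker parental orientation.
* No CMH test across replicates, no Fisher exact tests, no effective
  population-size estimation — the pipeline mirrors the per-replicate
  chi-square design it implements.
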