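---
title: "Models and methods: multiplexed proteome dynamics profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multiplexed proteome dynamics profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodyn)
library(dplyr)
```

## The experiment the package models

Multiplexed proteome dynamics profiling (mPDP) combines dynamic SILAC with
isobaric mass tagging. Cells grown in light medium are switched to heavy
medium at treatment start (and vice versa for the biological replicate), so
proteins synthesized before the switch — the *mature* pool — carry one SILAC
label and proteins synthesized during treatment — the *nascent* pool — carry
the other. Each sample (condition × replicate) additionally receives its own
isobaric reporter channel, so a single MS run quantifies both pools across
all conditions in biological duplicate. Because the two replicates carry
opposite label orientations, a spectrum's SILAC label determines *which*
pool it reports for each replicate's channels.

Under first-order kinetics with synthesis rate $s$ and degradation rate
constant $k$, after the medium switch at $t = 0$:

$$\mathrm{mature}(t) = M_0\, e^{-k t}, \qquad
  \mathrm{nascent}(t) = \frac{s}{k}\left(1 - e^{-k t}\right).$$

At steady state ($s = k M_0$) the nascent/mature ratio is
$r(t) = e^{kt} - 1$, which is what the turnover estimator assumes.

## Reporter-ion quantification

`filter_psms()` retains spectra with ion score > 15, precursor
signal-to-background > 4 and signal-to-interference > 0.5; all thresholds
are strict inequalities, so boundary values are rejected, and all are
configurable. `compute_ion_areas()` multiplies reporter intensities by the
ion accumulation time (ms), giving a measure proportional to ion counts.
`correct_isotope_purity()` solves the linear mixing system
$\mathrm{observed} = P \cdot \mathrm{true}$ for a supplied purity matrix
$P$, clipping negative components to zero. `adjust_interference()` de-mixes
an observed ratio under the explicit model
$\mathrm{obs} = \mathrm{s2i}\cdot\mathrm{true} + (1-\mathrm{s2i})\cdot
\mathrm{background}$; the background ratio defaults to 1 (an unregulated
background) and can be replaced by a per-experiment estimate. The exact
interference formula used in earlier isobaric-tag work is not public in
closed form, so this linear mixing model is stated explicitly rather than
hidden.

`bootstrap_protein_quant()` aggregates spectra by summing ion areas per
channel; the protein-level fold change is the ratio of sums. Confidence
intervals are percentile intervals (2.5/97.5) over 1,000 resamples of
spectra with replacement — the resampling unit is the spectrum — and are
reported only for proteins with more than three spectra. The resample count
and the percentile method are package choices; the seed is an explicit
argument and recorded by the caller. Proteins need at least two unique
peptide matches to be quantified at all.

For precursor-intensity (SILAC-only) quantification,
`silac_protein_ratio()` takes the median of valid peptide ratios (score >
15, length ≥ 6, least-squares pair fit ≤ 0.1, prior ion ratio ≤ 0.2);
undetermined ratios are excluded whenever at least one valid positive ratio
exists, and a protein with no valid ratio is reported unquantified rather
than zero. `impute_missing_abundance()` substitutes half of the smallest
detected abundance in the experiment for proteins missing in a paired
condition, and `donor_consistency_filter()` removes proteins whose effect
differs more than 8-fold between donors or rests on fewer than 3 spectrum
matches.

## The replicate-based significance framework

`mpdp_significance()` implements a five-step procedure on log2 fold changes
from two biological replicates:

1. **Median normalization** per condition × pool × replicate. When a large
   part of the nascent proteome is genuinely regulated, its own median is
   not a null reference; `use_mature_factors_for_nascent = TRUE` applies
   the mature pool's factors to the nascent pool instead.
2. **Binning by data quality**: proteins are sorted by the number of
   quantified spectrum-sequence matches (SSM) and cut into greedy
   consecutive bins of at least 300 proteins, the remainder merging into
   the last (highest-SSM) bin; ties break on the protein identifier so the
   binning is deterministic. With fewer than 300 proteins in total a single
   bin is used with a warning. Each protein's binning key is the *smaller*
   of its two replicate SSM counts — quality is limited by the weaker
   replicate; the combining rule is a package decision.
3. **Robust SD per bin** from replicate disagreement: the differences
   $d_i = (\mathrm{FC}_{1,i} - \mathrm{FC}_{2,i})/\sqrt{2}$ (the shortest
   distance to the equality line) are median-centred and their spread is
   half the distance between the 15.87 and 84.13 percentiles — ±1 SD under
   normality — with linear (type-7) interpolation between order statistics.
   Using replicate disagreement means the test does not assume that most
   proteins are unregulated.
4. **Z-tests and BH**: each replicate's fold change gets a two-sided
   Gaussian p-value against its bin's SD; Benjamini–Hochberg adjustment is
   applied to the pooled set across all bins, per condition, pool and
   replicate (the framework leaves open whether pools are pooled for
   adjustment; adjusting per pool keeps the two pools' very different
   regulation fractions from distorting each other).
5. **Dual-replicate call**: significant iff adjusted p ≤ 0.05 in both
   replicates, |log2 FC| > 0.37 in both, and the same sign in both. The
   0.37 cutoff is the log2 equivalent of a 30% change truncated to two
   decimals (log2 1.30 = 0.3785); it is configurable.

Degenerate noiseless bins (robust SD exactly 0) assign p = 1 to zero fold
changes and p = 0 to non-zero ones rather than failing.

## Turnover estimation

`decay_rate()` computes the through-origin least-squares slope of
$\log_e(r_{t_i}+1)$ on $t_i$,

$$k_{dp} = \frac{\sum_i \log_e(r_{t_i}+1)\, t_i}{\sum_i t_i^2},$$

dropping time points with undefined ratios from both sums.
`cell_cycle_correct()` subtracts the dilution rate $\log_e 2 / t_{cc}$ for
dividing cells; the cell-cycle time is a required argument with no default,
and corrected rates at or below zero are flagged as below the dilution
limit. Half-life is $\log_e 2 / k$. The $R^2$ reported by
`estimate_turnover()` is the uncentred coefficient of determination of the
through-origin model actually fitted, not of a free-intercept fit. QC
labels for four-point courses: *good* when ≥ 3 time points rest on ≥ 3
quantified peptides; *weak* when a fold change exists at ≥ 3 time points
but the good criterion fails (good takes precedence); *poor* otherwise.

## Thermal stability

### Melting curves (TPP-TR)

`fit_melting_curve()` fits

$$f(T) = \frac{1-\mathrm{plateau}}{1 + e^{\,b - a/T}} + \mathrm{plateau}$$

to fold changes relative to the lowest temperature. The exponent form is a
deliberate choice: the variant $e^{-(aT-b)}$ that sometimes appears in
print *increases* with temperature and never melts, contradicting both the
physical behaviour and the definition of a melting point; the $b - a/T$
form (used by the established thermal-profiling analysis it descends from)
is monotone decreasing. `melt_curve(form = "printed")` exposes the literal
alternative for comparison.

Fitting is bounded Levenberg–Marquardt with deterministic multi-start
(plateau ∈ {0, 0.1, 0.3}; $a$, $b$ from a logit-linear regression on
$1/T$), plateau constrained to $[0, 1)$, tolerance $10^{-10}$, at most 500
iterations; the lowest-RSS start wins, so there is no randomness. The
melting point solves $f(T_m) = 0.5$ in closed form,
$T_m = a / \left(b - \log\frac{0.5}{0.5-\mathrm{plateau}}\right)$,
undefined when plateau ≥ 0.5; tests verify it against numerical
root-finding. The slope at the steepest point is minimised numerically over
the measured range.

### Melting-point shifts

`tm_shift_significance()` evaluates proteins whose four curves (vehicle and
treatment in two replicate pairs) all have $R^2 > 0.8$ and whose vehicle
plateaus are < 0.3. Per replicate pair, ΔTm = Tm(treatment) − Tm(vehicle)
is tested with a Z-test against a robust percentile SD estimated within
bins of at least 300 proteins keyed on the pair's minimum curve slope
(shallowest first — shallow curves give noisy melting points), with
median-centring per bin, then BH over the full set. A shift is significant
iff one adjusted p < 0.05 and the other < 0.1, both pairs shift in the same
direction, both |ΔTm| exceed the vehicle-vehicle melting-point difference,
and the minimum slope of each pair is < −0.06. The z-test's centring and SD
estimator are package concretizations; the criteria themselves are the
published ones.

### Dose-response (2D-TPP)

A protein is potentially stabilized when its apparent stability at the top
concentration exceeds 3/2, potentially destabilized below 2/3, and
otherwise not analysed. Fold changes are min-max transformed to [0, 1]
(flat series map to the vehicle endpoint) and fitted with
$Y = 1/(1 + 10^{(\log EC_{50} - x)\cdot\mathrm{slope}})$ on
$x = \log_{10}$ concentration, vehicle excluded. The fit is accepted at
$R^2 > 0.8$; $\mathrm{pEC}_{50} = -\log EC_{50}$. The validity rule is
implemented by its substance: a pEC50 is invalid when the derived EC50 lies
*below the lowest non-vehicle concentration tested*, i.e. the midpoint
would be an extrapolation outside the dose range (stated sign conventions
for this rule vary; the extrapolation criterion is the meaningful one).

## Classification of chaperone dependence

`classify_dependence()` keys on significant *down*-regulation:
mature-pool downregulation at any time point ⇒ *constitutive* dependence,
irrespective of the nascent pool (so a protein mature-down at one time and
nascent-only-down at another is constitutive — no tie-break needed);
nascent-only downregulation ⇒ dependence *during synthesis*; otherwise not
regulated. Stabilized (upregulated) proteins are reported via an `any_up`
flag rather than a class, since the classifier is down-only. Proteins seen
in a single pool are classified from that pool and flagged `partial`.
`fisher_enrichment()` tests annotation enrichment with the exact
hypergeometric two-sided p and reports the sample odds ratio $ad/bc$.

## The synthetic-data generator

`simulate_mpdp_experiment()` emulates: the label-swap duplicate design with
one reporter channel per condition × replicate; exponential decay of the
mature pool and saturating accumulation of the nascent pool; treatment
effects as multipliers on $k$ and $s$ acting from $t = 0$; long-tailed
spectral counts (negative binomial, mean 12, dispersion 1.2, shifted by 1)
to exercise the ≥ 300 binning; multiplicative lognormal reporter noise
(default SD 0.25 on the log2 scale, a typical replicate spread for
reporter-ion quantification); a per-spectrum ionization scale; and quality
fields drawn so that roughly a fifth of spectra fail the quantification
filters. Default conditions: 6 h treatment, half-lives lognormal around a
20 h median — typical of a fast-growing lymphocyte line. All generators
are pure functions of (configuration, seed) and ship ground-truth tables
sharing the protein identifiers.

What the generator does **not** model: amino-acid recycling and partial
label incorporation (full incorporation is assumed), spectrum-level effects
(isotope envelopes, co-isolation structure — interference is only
represented through the s2i quality field), peptide-specific ionization
biases that persist across samples, and batch or gradient drifts. Passing
tests on synthetic data therefore demonstrate the correctness of the
estimators and decision rules under the stated noise model, not robustness
to every artefact of real LC-MS/MS data.

`simulate_tr_experiment()` draws melting points around 52 °C (SD 2.5),
curve steepness within the range accepted by the slope filter, plateaus
below 0.12, and emits model fold changes plus Gaussian noise over 12
temperatures spanning 42.0–63.9 °C; it emits the model curve directly (the
model is already relative to the lowest temperature), so noiseless data are
recovered exactly by the fitter. `simulate_dose_response_table()` generates
apparent-stability series over vehicle plus 0.1/1/5/20 µM with asymptotic
fold changes 3 (stabilized) and 1/3 (destabilized).

## Numerical and scale choices

* Quantile computation everywhere uses linear interpolation (R type 7).
* Natural log for kinetics, log2 for fold changes, log10 for dose-response;
  conversions happen at the interfaces.
* Suite problem sizes: the binning contract runs on 5,000 proteins;
  robust-SD calibration on 100,000 pairs; the null and recovery runs on
  1,200–2,000 proteins; thermal shift testing on 400–650 proteins × 4
  curves. These sizes give stable empirical fractions while keeping the
  whole suite around a minute.
* End-to-end recovery tests inject effects into proteins with half-lives of
  5–25 h: a degradation-rate change cannot manifest within a 6 h window for
  a 100 h half-life protein, so positive controls are drawn from the
  kinetically observable range.

## A worked run

```{r example}
specs <- sim_protein_specs(800, seed = 42)
hits <- head(specs$protein_group[log(2) / specs$k <= 25 & log(2) / specs$k >= 5], 10)
sim <- simulate_mpdp_experiment(
  n_proteins = 800, seed = 42, specs = specs,
  effects = tibble::tibble(protein_group = hits, condition = "treated", k_mult = 4)
)
res <- run_mpdp(sim$psms, sim$design)
res$significance |>
  filter(significant) |>
  count(pool, direction)
```

```{r plot, fig.width = 6, fig.height = 4}
plot_replicate_scatter(res$significance)
```

## Known limitations

The framework assumes exactly two biological replicates; the robust SD is a
single number per bin (no per-protein variance model, no moderated
variance); the turnover model ignores label recycling and synthesis-rate
fitting; the TR global normalization across experiments is not applied to
synthetic data by default; and melting/dose-response fits are per protein
with no information sharing across proteins.
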