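---
title: "Methods: blood methylation analysis of weight-loss response"
author: "methresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood methylation analysis of weight-loss response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methresp)
```

This vignette documents the models and procedures implemented in
`methresp`, the parameters that matter, the deliberate design choices made
where several defensible options existed, and what the synthetic-data tests
do and do not establish about real cohorts.

## The data model

The central object is a `MethylationExperiment`
(a `RangedSummarizedExperiment`): a probe × sample matrix of beta values
(methylation fractions in [0,1]) with an optional detection p-value matrix
of the same shape, probe coordinates and QC flags as row ranges, and the
phenotype table (subject, timepoint T0/T18, sex, age, BMI, weights,
intervention arm) as column data. Every subject contributes two samples,
baseline (T0) and post-intervention (T18).

## Probe QC and normalization

A probe is excluded when its detection p exceeds 0.01 in **strictly more
than** 1% of samples; the boundary case is retained. Cross-reactive and
SNP-overlapping probes are never removed — they are flagged and the flags
travel into every result table, leaving the judgement to the reader.

Quantile normalization forces each sample onto the common distribution of
mean order statistics (ties within a sample receive the mean of their tied
ranks' reference values; delegated to `limma::normalizeQuantiles`). This is
plain column-wise normalization on the beta matrix: probe chemistry types
(type I/II) are not modelled here, a deliberate simplification relative to
array-specific pipelines. Missing betas are disallowed — quantile
normalization is ill-defined on ragged columns.

## Cell-type deconvolution and adjustment

Whole blood is a cell mixture, and composition differences are a classic
confounder of blood EWAS. `estimateCellProportions()` performs
Houseman-style reference-based deconvolution: per sample, non-negative
least squares of the observed marker betas on the reference profiles,
followed by renormalization onto the unit simplex. This constrained
projection is deterministic and needs no quadratic-programming dependency;
on noiseless mixtures it recovers proportions to numerical precision, and
with logit-scale noise of SD 0.02 the mean absolute error stays below 0.05
(both asserted in the suite).

`compareComposition()` runs paired Wilcoxon signed-rank tests on the
T18 − T0 proportion differences per cell type (zeros dropped; exact null
for ≤ 25 non-zero pairs, normal approximation with continuity correction
above). `adjustForComposition()` residualizes each probe on the proportion
covariates (intercept + all but one cell type, the last being collinear
with the simplex constraint) and adds back the probe's grand mean, so
per-probe means are preserved exactly and only composition-attributable
variance is removed; values are clipped to [0,1] afterwards.

Two caveats are worth stating. First, residualization on estimated
proportions partially absorbs a true group effect whenever group membership
correlates with composition — adjustment trades confounding bias for
attenuation. The suite's confounded-design test uses mild confounding
(proportion difference ≈ 0.07 in one cell type) where the attenuation is
well under the ±0.02 recovery tolerance. Second, adjustment on *known*
covariates replaces latent-factor approaches (surrogate variable analysis);
estimating hidden structure is out of scope. Downstream analyses accept
either quantile-normalized or composition-adjusted betas; adjusted is the
recommended default, but the generator-calibrated recovery benchmarks run
on unnormalized betas, because quantile normalization and residualization
each attenuate a planted beta-scale difference by ~0.01 and the benchmark
targets the caller, not the preprocessing.

## Responder definition and DMR calling

Subjects (males only by default, reflecting a heavily male cohort — the
default generator plants 10 women in 120 subjects) are ranked by relative
weight change; the `nPerGroup` most negative are responders, the most
positive non-responders, with boundary ties broken by ascending subject id.
Age matching is implemented as a post-hoc balance check (flag when group
mean ages differ by more than 5 years, configurable), not as pair matching:
no matching algorithm is prescribed for this design, and a transparent
check is preferable to an arbitrary one.

DMR calling proceeds cluster → segment → test:

* **Clustering**: maximal runs of same-chromosome probes with consecutive
  gaps ≤ 1000 nt (inclusive boundary), at least 3 probes.
* **Segmentation**: recursive binary splitting of the per-probe
  group-difference signal at the boundary maximizing the difference of the
  two sub-segments' means; recursion stops when a segment is shorter than
  `2 × minProbes` or no split increases |deltaM|. This is a documented
  stand-in for metilene-style segmentation, whose exact stopping rule is
  not reproduced here; region callers legitimately differ, and the suite
  therefore validates recovery of planted truth rather than equivalence to
  any specific tool.
* **2D-KS test**: each candidate region becomes two point clouds with one
  point per sample per probe, x = genomic position min–max scaled into
  [0,1] (so both axes are comparable — exposed as `scalePositions`),
  y = beta. The statistic is the Fasano–Franceschini construction: the
  maximum over all data points and all four inclusive quadrant
  orientations of the absolute difference in empirical quadrant
  probabilities. The p-value permutes **sample** labels, never individual
  points — points from one sample are dependent — with
  p = (1 + #{D_perm ≥ D_obs}) / (nPerm + 1). An asymptotic
  Fasano–Franceschini approximation is available for quick screens.
* **deltaM** is the difference (group A − group B) of the group means of
  per-probe mean betas, unweighted across probes.
* **Multiple testing**: Benjamini–Hochberg across all candidate regions.

Combining timepoints (`timepoints = c("T0","T18")`) treats each subject's
two samples as replicates, doubling each group's point cloud without any
dependence correction; this boosts power at the cost of anti-conservative
region p-values and is flagged in the documentation accordingly.

### Numerical behaviour of the permutation p

D is a difference of count fractions, hence discrete, and permuted values
tie with the observed one. Counting ties fully (as above) gives a *valid,
conservative* test — under a fully null cohort the empirical rejection rate
at any α stays below α (asserted in the suite), and the p-value
distribution is stochastically larger than uniform (observed mean ≈ 0.62 at
10 vs 10 samples × 5-probe regions). The tie-corrected mid-p
(ties counted half) is additionally reported per region: it is centred on
uniform (mean ≈ 0.5) and is the right quantity for calibration
diagnostics, while the conservative p feeds inference and BH adjustment.
Exact uniformity is unattainable for any discrete statistic at these group
sizes; the package asserts validity plus mid-p centering rather than a
strict uniformity it cannot honestly deliver.

For throughput, permutation can stop early once a configurable number of
exceedances has accumulated (default 32): clearly-null candidates finish
after a few dozen permutations, the sequential p (1+k)/(1+B_done) remains
valid, and small p-values are untouched because those candidates never
trigger the stop.

## Single-CpG tests

`dmpSingleCpG()` is the per-probe companion: two-group mode is the
pooled-variance t-test (equivalently OLS on a group indicator), continuous
mode the regression-slope t-test, paired mode the paired t on
within-subject differences; all vectorized across probes, BH-adjusted
q-values included. Zero-variance probes are flagged with p = 1 rather than
propagating NaNs.

## EWAS with combined correlations

For each probe, baseline (T0) methylation is correlated with relative
weight change twice — Pearson for linearity, Spearman for monotonicity —
and the evidence is combined as the geometric mean of the two two-sided
p-values, computed in log space so p < 1e-300 does not underflow. The
combined p always lies between the component p-values. The reported
combined correlation is the arithmetic mean of r and rho — a deliberate
definition, since "combined correlation" admits several readings —
with a sign-concordance flag; discordant-sign probes are retained, flagged.
Pearson p-values use the t transform with n − 2 df; Spearman p-values are
exact for n ≤ 9 without ties (via `cor.test`) and t-approximated with
average ranks otherwise — at moderate n this deviates slightly from the
AS89 algorithm, which matters only in the far tail. Geometric-mean
combination of two dependent p-values is *not* uniform under the null
(it is mildly anticonservative at conventional thresholds), which is why
results are reported as threshold tiers mirroring common practice rather
than as calibrated significance statements; the null tier rate is
quantified in the tests.

Phenotype correlations reuse the same combined statistic for candidate
probes against clinical traits (levels at each timepoint, and T18 − T0
changes against baseline methylation), BH-corrected across the whole table.
Paired T0/T18 trait changes are summarized with the paired t-test; a
non-zero constant shift (zero variance of differences) is reported as p = 0
with a degeneracy flag instead of failing.

Gene annotation extends each gene 1500 nt upstream on its own strand
(clipped at position 1; unknown strand treated as '+' with a warning) and
reports every extended gene overlapping a feature, 1-based inclusive.
BED I/O converts to and from 0-based half-open coordinates.

## Prediction

Four methylation scores are built from the EWAS table by correlation sign ×
combined-p threshold (10⁻³, 10⁻⁴); a score is the unweighted mean beta over
the set, oriented so that the direction predicting success is consistent
(higher score → more loss for negatively-correlated sets). ROC curves use
every cut-point with the midpoint tie convention, so the trapezoidal AUC
equals the Mann–Whitney concordance exactly (oracle-checked to 1e-12).

The benchmark is the best linear `x·age + y·BMI` score. Since ranking
depends only on the direction of (x, y), the search space is one angle:
`(cos θ, sin θ)` over a 721-point grid on [0, 2π) is exhaustive up to
resolution, and the winner is rescaled to x = −1 for comparability. Success
labels default to responder-group membership, since "successful
weight loss" has no canonical numeric cutoff in this design; a percent-loss
cutoff can be substituted by constructing the design manually.

No train/test split is performed by default — deliberately mirroring the
two-stage design this pipeline models, where CpGs are selected on the same
samples used for ROC evaluation. The resulting AUCs are optimistically
biased; the output table carries this note, and the suite turns the bias
itself into a property: the grid-maximized age/BMI AUC on label-shuffled
data at n = 20 averages well above 0.5 (and below 0.8), quantifying the
in-sample selection ceiling instead of advertising inflated performance.

## Chromatin states and gene-set enrichment

Features are intersected with user-supplied per-tissue chromatin-state
segmentations (BED4): per tissue the state with the largest bp overlap
(ties multi-reported), per tissue group the modal state across member
tissues. No external segmentations are bundled.

Gene-set enrichment corrects for the array's probe-per-gene bias by
resampling probes, not genes: the null draws `|hits|` probes uniformly from
the probe universe — so a gene covered by 50 probes enters null draws 50×
more often than a single-probe gene — maps them to genes and counts the
set overlap; p = (1 + #{null ≥ observed})/(B + 1), BH across sets. The
suite demonstrates the point of the correction: richly-probed gene sets
that a naive gene-level hypergeometric flags on random hits are not flagged
by the probe-resampling null. Ontology hierarchies are not bundled; gene
sets arrive as plain TSV.

## The synthetic-cohort generator

The generator exists so every stage can be tested against known truth. Its
defaults emulate the study conditions this pipeline targets: 120 subjects
(90% male, ages ~49 ± 9.3, BMI ~30.2 ± 3.3, baseline weight
~90.3 ± 11.5 kg), T0/T18 samples, relative weight change with overall mean
≈ −4% (≈ −3.65 kg) and spread ≈ 5.2 kg, extreme tails near −16% and +2.4%,
probe clusters with intra-cluster spacing ~100 nt (≤ 1000) and
inter-cluster gaps > 1000 nt, a six-population leukocyte mixture
(neutrophil-dominated Dirichlet), and planted effects at the scales the
pipeline is meant to detect: region differences |deltaM| ≈ 0.04–0.13 and
baseline correlations |r| ≈ 0.34–0.42.

Design choices worth knowing:

* **Betas stay in (0,1) by construction**: probe means are mixed on the
  beta scale, then Gaussian noise is added on the logit scale and
  transformed back — no rejection sampling, no clipping artefacts.
  `noiseSd` is the logit-scale SD (0.12 ≈ 0.03 beta-scale at
  mid-methylation). The real data's noise magnitude is not published;
  defaults are chosen so the planted effect scales are detectable at
  n = 10–120, which is what the recovery tests require.
* **Weight-correlated CpGs** add c·(standardized weight change) on the
  logit scale with c = σρ/√(1−ρ²), hitting the target correlation in
  closed form given the noise SD.
* **Responder labels follow the realized ranking**: tail subjects are
  planted at −16%/+2.4%, but the truth labels are assigned to the
  empirically most extreme males using the same ranking and tie rule the
  selection operation applies. This mirrors the study design itself — the
  responder groups *are* the observed extremes — and keeps planted effects
  and recoverable groups consistent even when a background subject
  out-loses a planted tail subject. A consequence: the realized
  non-responder group mean sits above +2.4% whenever background subjects
  with larger regains displace planted ones.
* **Background weight-change SD defaults to 4.6%** so that the full
  mixture (background + both tails) reproduces the target overall spread
  of ≈ 5.7% ≈ 5.2 kg.
* **Cell references are well-separated by construction** (each marker
  probe hypo- ~0.15 or hyper-methylated ~0.85 per cell type, pairwise mean
  absolute difference ≈ 0.35), making deconvolution identifiable.
* **Determinism**: a configuration (including its seed) reproduces every
  output bit-identically; sub-steps draw from seeds derived by fixed
  offsets.

What passing these tests shows — and does not. The generator produces
clean, additive, approximately logit-Gaussian signal with exchangeable
noise. It does not emulate probe-type chemistry differences, batch or chip
effects, genetic (SNP-driven) methylation structure, age/sex methylation
gradients, or realistic linkage between nearby probes beyond shared means.
Recovery of planted truth therefore validates the *implementation* of each
method under its own assumptions, not the methods' robustness to the full
messiness of real array data.

## Problem sizes in the checks

The automated checks run at deliberately chosen scales: null calibration on
120 subjects × 10,000 probes (one full-permutation diagnostic run plus 20
independent null cohorts for the zero-false-positive check at 199
permutations each); DMR recovery with 50 planted 5-probe regions among
3,000 probes at 999 permutations; EWAS ranking with one planted CpG among
5,000 nulls at n = 120 across 20 (tests) / 10 (acceptance script) seeds;
prediction across 20 seeds of 60-subject cohorts. These sizes give stable
pass/fail behaviour for the stochastic assertions while keeping a complete
run in the minutes range on one CPU.

## Known limitations

* Region segmentation is a documented stand-in, not a re-implementation of
  any specific DMR caller; boundary placement on gradual signals differs
  between callers.
* The combined-timepoint replicates mode ignores within-subject dependence
  by design and inherits that caveat.
* Geometric-mean p combination is a ranking device, not a calibrated test.
* Composition adjustment attenuates group effects in proportion to
  group–composition correlation; under strong confounding no linear
  correction recovers the effect unbiasedly.
* In-sample predictor evaluation inflates AUC; the reported selection-bias
  ceiling quantifies, but does not remove, that inflation.
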