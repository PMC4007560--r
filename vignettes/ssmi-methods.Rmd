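---
title: "Calibrating microarray probes against RNA-Seq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating microarray probes against RNA-Seq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmi)
```

## The problem

Microarray probes report fluorescence intensity, not transcript abundance.
Two probes for the same gene can disagree wildly: one may cross-hybridize to
a paralog, another may sit near the background floor, a third may respond
linearly but with its own slope and offset. RNA-Seq TPM values, by contrast,
track absolute abundance well. When the same RNA aliquots have been profiled
on both platforms, the sequencing data can serve as ground truth for the
array: it tells us *which* probes to trust, and *how to re-express* a
trusted probe's intensities on an absolute scale.

`ssmi` implements that program in three stages, plus the supporting
normalization and the evaluation metrics used to validate it, and a
synthetic-data generator so the entire pipeline is testable without any
external download.

## Stage 1 — normalization

**Sample scaling on non-differentially-expressed genes**
(`tbt_normalize`). Library-size scaling is biased when one sample group
genuinely expresses more of some genes; the remedy is to scale each sample
by its total signal over genes *not* differentially expressed between the
two groups (here: neocortex vs non-neocortex). The original method used a
Bayesian DE caller; this package uses a per-gene Wilcoxon rank-sum test with
Benjamini–Hochberg FDR < 0.05, which is distribution-free and has no extra
dependencies — the choice matters little because the flag only selects the
scaling gene set. Scale factors are normalized to mean 1 (they are otherwise
only identifiable up to a constant), and one global multiplicative constant
restores the matrix-wide total of `log2(value + epsilon)` exactly (solved by
`uniroot` to machine precision rather than by a first-order approximation).
Whether the conservation constraint is matrix-wide or per-sample is
genuinely ambiguous in the source material; matrix-wide is the default and
`rescale_scope = "sample"` exposes the alternative.

**Empirical-Bayes batch adjustment** (`combat_adjust`). Donor-of-origin is
treated as a batch with per-gene location and scale effects, removed by the
parametric empirical-Bayes model of Johnson, Li & Rabinovic (2007): per gene,
standardize by the batch-size-weighted grand mean and the pooled residual
standard deviation (denominator *N*); per batch, shrink observed means and
variances (denominator *n − 1*, matching the reference implementation)
toward normal / inverse-gamma method-of-moments priors by iterating the
posterior updates to a fixed point (default `tol = 1e-4`, `max_iter = 500`;
non-convergence is an error with diagnostics, not a silent fallback).
Degenerate hyperpriors — all batch means identical (`tau² = 0`) or all batch
variances identical (`S = 0`) — are treated as point-mass priors, which is
their analytic limit. Genes with zero pooled variance pass through
unadjusted and are reported. One consequence of the published model worth
knowing: it is *not* exactly idempotent on finite noisy data. A second
application re-estimates and re-shrinks the sampling noise of the batch
moments, and the *N* vs *n − 1* denominators rescale deviations by a factor
of order *k/N*. The test suite therefore checks idempotence in the exact
(no gene-specific noise) regime, where the fixed point is reached in one
application up to that vanishing rescale.

## Stage 2 — probe quality control

Each probe is scored by the Pearson correlation `r` between its log2
intensities and its gene's log2 TPM values across the training samples
(`probe_correlation`). Only positive correlation is evidence the probe
tracks its gene, so the default test is one-sided
(`t = r sqrt((n−2)/(1−r²))` on `n − 2` df); a two-sided option exists.
P-values become Storey-style q-values (`qvalues`): the null proportion π₀ is
estimated by averaging `#{p > λ}/(m(1 − λ))` over λ = 0.05, …, 0.90 (this
smoother-free grid average is fully specified so results are deterministic),
and q is π₀ times the Benjamini–Hochberg step-up quantity, capped at 1.
A probe passes when `r > 0` and `q < 0.1` (`assign_pass`); probes with
undefined correlation fail, and probes whose gene is absent from the
RNA-Seq matrix are recorded with `pass = NA` rather than dropped.

Per gene, three designations are assigned (`designate_probes`): *best*
(maximal `r`), *worst* (minimal `r`), and *highest* (maximal mean expression
across region means — the classical intensity-only selection rule the
correlation-based choice is compared against). Ties break lexicographically
by probe id so reruns are stable.

`flag_bright_probes` is a deliberately simple surrogate for the published
selection of probes far brighter than their gene's abundance justifies: a
least-squares line of mean log2 intensity on mean log2 TPM across probes,
flagging positive residuals beyond 3 residual standard deviations. It is a
screening diagnostic, not part of the pass/fail path.

## Stage 3 — quantile-anchored scaling (SSMIs)

For each passing probe, `fit_scaling` computes the 5th and 95th quantiles of
its log2 intensities and of its gene's log2 TPM values over the training
samples (quantile type 7 — linear interpolation between order statistics —
stated explicitly because the anchors must be reproducible), then solves the
two-point line through the anchor pairs:

    m = (q95_seq − q05_seq) / (q95_array − q05_array)
    b = q05_seq − m · q05_array

`apply_scaling` maps any intensity matrix through `m·x + b`, yielding
sequencing-scaled microarray intensities in log2 TPM units. By construction
the anchors align exactly on the training samples; both ordered anchor pairs
make `m > 0` automatic, and a probe with a degenerate intensity range is
excluded as unscalable. The fit is performed on data normalized up to but
*not* including the cross-donor batch adjustment, so a held-out donor
remains genuinely independent; batch adjustment of the scaled matrix is an
optional reporting step afterwards.

Two conventions matter for comparisons: parameters are emitted for *all*
passing probes, but between-method summary comparisons use only each gene's
best probe; and the RNA-Seq anchor quantiles are computed over the same
training samples as the intensity anchors.

## Evaluation battery

* `replicate_correlations` — Pearson correlation over genes for every pair
  of samples sharing donor, region and hemisphere.
* `presence_summary` — present-call concordance at 5%/50%/95% sample
  thresholds (array: vendor flags; RNA-Seq: at least one aligned fragment).
* `foldchange_concordance` — draws (gene, region A, region B) triples
  uniformly *with replacement* (well-defined for any universe size),
  regions distinct and unordered, computes the log2 fold change of region
  means in both matrices, and reports the Pearson correlation across draws;
  fully seeded.
* `per_gene_reproducibility` / `binned_reproducibility` — per-gene
  between-donor correlation of 29-region mean profiles, binned into 20
  near-equal groups (remainder on the leading bins) by mean expression or
  transcript length, with per-bin mean and SEM.
* `region_anova` — per-gene one-way fixed-effects ANOVA across the regions
  of one class, computed vectorized from sums of squares (cross-checked
  against `stats::aov` in the tests), Bonferroni-corrected counts; a gene
  with zero total variance gets `p = 1` by convention.
* `subsample_stability` — reruns QC (and optionally the fit) on
  region-stratified subsets of growing size. "Carefully selected" subsets
  are drawn one-per-region-class first, then one-per-region, then uniformly:
  transcriptional diversity is what powers the correlation test.

## The synthetic-data generator

`simulate_dataset` emulates the study design: 29 regions (22 neocortex, 7
non-neocortex) × 2 hemispheres × 2 replicates × 2 donors = 232 samples, with
donor doubling as batch. Defaults are chosen once to put the generator in
the regimes that matter and are not re-tuned:

* **Abundance**: baseline log2 abundance ~ N(1, 2.5), so roughly a third of
  genes fall below TPM = 1 — the low-expression regime where both platforms
  degrade.
* **Regional structure**: every gene carries small per-region effects
  (sd 0.1 neocortex / 0.3 non-neocortex) and 30% of genes carry strong ones
  (0.25 / 1.0). Pervasive regional variability is the premise of the whole
  method — without cross-sample variance there is nothing to correlate — and
  non-neocortical regions are the transcriptionally distinct ones.
* **Donor effects**: per-gene location shifts (sd 0.3) and noise-scale
  multipliers (log-normal sd 0.2), so the batch adjustment has both a
  location and a scale job to do.
* **Sequencing**: expected fragments per sample 1e5 (a deliberately
  scaled-down working depth; real experiments run ~3×10⁷), with Poisson
  counting noise and TPM computed from counts. Columns of the TPM matrix
  sum to 10⁶ exactly. With `count_noise = FALSE` the generator emits the
  exact expected TPM — the noise-free closure regime in which the fit must
  recover every probe's true parameters to 1e-9.
* **Probes**: ~1.8 probes/gene. Each probe's true line is drawn with slope
  m ~ lognormal(log 1.41, 0.51) (about half of slopes between 1 and 2) and
  an intercept derived from a *pivot*: the probe's expected intensity is
  anchored to its gene's prior abundance with jitter sd 1.5, reproducing the
  moderately tight mean-intensity-vs-mean-TPM cloud (correlation ≈ 0.78)
  seen between real platforms. The anchor uses the abundance *prior*, not
  the realized tissue profile, so probe parameters are physical properties
  of the probe and transfer across simulated "tissues" sharing a seed — the
  property that makes cross-experiment transfer of scaling parameters
  meaningful. Intensities are softplus-floored at log2 intensity 1
  (background) and clipped at 14 (saturation). 10% of probes track a
  different random gene (off-target); 2% emit constant near-saturation
  intensity (the bright, histone/keratin-like failure mode).
* **Noise**: array replicate noise sd 0.3, sequencing replicate noise sd
  0.2 in log2 space, chosen to put array replicate correlations near
  real-world values; at the scaled-down depth the sequencing replicate
  correlation is dominated by counting noise instead, which is intended.

What the generator does **not** emulate: gene-length bias in counts
(lengths are simulated log-normally and used only as a binning key),
isoform structure, probe-sequence-driven cross-hybridization (off-target
assignments are random, so off-target probes co-express with their assigned
gene only by chance), spatial array artifacts, and vendor preprocessing.
Passing tests therefore demonstrate the statistical machinery under the
assumed noise model, not robustness to those real-data pathologies.

## Numerical choices and degenerate inputs

* log2 offset `epsilon = 2⁻¹⁰` by default (configurable, and `0` is allowed
  when no zeros are present): small enough not to distort values at
  TPM ≥ 1; its inverse transform clips at zero.
* Quantiles: type 7 everywhere, stated in the scaling-table header.
* Scaling tables are written with 15 significant digits so read-backs agree
  to at least 12; failing probes keep their QC columns with empty `m`/`b`.
* Constant genes: pass through both normalizations unchanged (logged);
  constant probes are unscalable (logged); zero-variance correlation inputs
  give `r = NA`, `p = 1` and fail QC.
* All resampling (fold-change draws, subsampling) and the generator run off
  explicit integer seeds; the generator restores the caller's RNG state.
* Pipeline outputs carry a header comment with package version, a config
  hash and the seed; reruns are byte-identical.

## Problem sizes used by the test suite

The default generator (2000 genes, ~3600 probes, 232 samples, depth 1e5)
runs the full fit-and-evaluate pipeline in a few seconds, so the test suite
exercises everything at full design scale: the false-discovery and power
checks pool ten generator runs at 115 training samples, the oracle checks
use a 10⁵-draw permutation test and small hand-checkable toys, and the
directional reproductions (scaling transfer, batch-adjustment effect on
fold-change concordance, expression-binned reproducibility, pass-rate
growth with training-set size) each use one seeded study-scale run.

## Known limitations

* At the scaled-down sequencing depth, counting noise dominates the RNA-Seq
  side for low-expression genes; absolute values of concordance metrics are
  correspondingly lower than at production depth, while their *directions*
  (what the tests assert) are preserved.
* The off-target pass rate under q < 0.1 is bounded below by the implied
  p-value cutoff of the FDR machinery and inflated further by chance
  co-expression between a probe's assigned and tracked genes; correlation
  QC cannot, even in principle, fail an off-target probe whose off-target
  happens to co-express with the assigned gene. The FDR of the *passing
  set* is the controlled quantity.
* The linear response model is exact in the generator by construction;
  real probes saturate and flatten at the extremes, which the 5th/95th
  anchors absorb only partially. Nonlinear (spline) response models are out
  of scope.
* The bright-probe screen is a simplified residual rule on grand means, not
  the published selection procedure, and is exposed as a diagnostic only.
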