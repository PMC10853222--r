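---
title: "Evaluating DNA methylation episignatures with a consensus kNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA methylation episignatures with a consensus kNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An *episignature* is a published set of CpG probes whose joint methylation
pattern is claimed to discriminate carriers of pathogenic variants in a given
gene from unaffected individuals. Diagnostic laboratories would like to use
such signatures to arbitrate variants of uncertain significance (VUS), but a
probe list trained on one cohort may not generalise: discovery sets are often
tiny (sometimes under ten samples against hundreds of thousands of probes),
so overfitting and winner's-curse effects are a constant threat. The honest
question is therefore not "does the signature separate its own training
data?" but "what sensitivity and specificity does the published probe list
achieve on samples it has never seen?".

`episigval` answers that question with a deliberately simple, neutral
classifier. Because the original prediction models are rarely shared, the
only portable artifact of a published episignature is its probe list. The
package therefore evaluates every signature with the same machinery:

1. **Quality control.** A probe is removed when its detection p-value
   exceeds 0.01 in strictly more than 5% of samples; a sample is flagged
   when strictly more than 1% of its probes fail detection or when its
   methylation distribution is an outlier.
2. **Confounder adjustment.** Whole-blood methylation depends strongly on
   age, sex and cell composition, so per-probe ordinary-least-squares
   residuals of β on these covariates replace raw β values.
3. **Reproducibility of the effect.** For each signature probe the gap
   Δβ = mean(case β) − mean(control β) is computed; the fractions of probes
   with |Δβ| strictly above 0.05 and 0.10 summarise whether the published
   effect is present at all in the new cohort.
4. **Consensus kNN with leave-one-out.** A multiclass k-nearest-neighbour
   classifier over *all* syndromes and controls simultaneously predicts each
   validation sample from all remaining ones. A sample is assigned a class
   only when at least *m* of its *k* nearest neighbours agree ("m/k"
   consensus, from strict 2/2 up to 5/5, with 3/4 and 4/5 tolerating one
   discordant neighbour); otherwise no call is made. Sensitivity,
   specificity and inter-syndrome specificity are reported with exact
   (Clopper–Pearson) binomial confidence intervals.
5. **Diagnostics and VUS calls.** PCA and hierarchical-clustering summaries
   of the signature-probe residuals expose intermediate profiles, and test
   samples (VUS and clinical hypotheses) are classified against the full
   validation set with the 3/4 parametrization.

## The classifier and its conventions

The kNN is intentionally unweighted — every probe of the signature
contributes equally through the Euclidean distance — because with roughly
ten samples per syndrome anything more flexible would reintroduce
overfitting, exactly what the evaluation is supposed to expose. Three
conventions matter for the arithmetic:

* **No-calls.** A case that receives `no_call` (or the wrong class) is a
  false negative. A control that receives `no_call` is still a true
  negative: only an actual syndrome assignment breaks specificity. The same
  convention applies to inter-syndrome specificity. A flag
  (`no_call_as_negative = FALSE`) switches to the stricter accounting.
* **Ties.** Equidistant training samples are ordered by ascending training
  index, and a consensus where two labels both reach *m* votes yields
  `no_call`. Both rules are deterministic so that every reported number is
  bit-reproducible.
* **X-linked genes.** Female carriers of X-linked syndromes are expected to
  present attenuated signatures, so they are excluded from that signature's
  sensitivity denominator *and* from its training folds by default
  (`include_female_carriers = TRUE` restores them). Whether such carriers
  should stay in training folds is genuinely unsettled; excluding them keeps
  the training clusters homogeneous, which is the conservative choice for a
  validation exercise.

Consensus strictness is monotone by construction: a sample positive at
`m2/k` is positive at `m1/k` for any `m1 ≤ m2`, so sensitivity can only
decrease as the required consensus grows. This is a deterministic property
of the call rule, not an empirical observation, and the test suite checks it
mechanically on the per-sample call tables.

## Confounder adjustment: joint versus controls-only fitting

`residualize()` fits, for every probe, β ~ intercept + age + sex + cell
composition (one of the six cell fractions is dropped because they sum to
one; constant covariates are dropped as carrying no information; genuine
collinearity raises an error naming the offending columns). By default the
model is fitted on **all** samples jointly, which mirrors how large
validation studies process their data: when a hundred carriers spread over
ten syndromes sit next to controls and test samples, no single syndrome
dominates the fit and the coefficient estimates are essentially clean.

At the scale this package's synthetic studies run — one to four syndromes of
ten cases against 25 controls — that reasoning breaks down. Cases are then
15–30% of the design, and any chance correlation between carrier status and
a covariate lets the covariate coefficients absorb part of the episignature
itself; we measured runs in which a single high-leverage case lost two
thirds of its effect and entire cohorts in which specificity collapsed,
purely through this mechanism. `residualize(fit_samples = <controls>)`
estimates the coefficients on controls only and applies them to everyone,
which makes the adjustment unbiased with respect to case status at any
cohort size. The package's own reproduction runs therefore use
controls-only fitting; the joint default remains because it is the
procedure a large study would (correctly) use.

## The synthetic cohort generator

Real episignature cohorts are clinical data and are not redistributable, so
the generator produces cohorts with the statistical structure the evaluation
assumes; it is first-class, tested code, and its defaults are the study
conditions of the package's reproduction runs:

* **Cohort layout.** 10 carriers per syndrome, 25 controls, optional VUS
  carriers per syndrome. Controls mirror the cases' sex and (jittered, sd
  2 y) age distribution — validation studies recruit age- and sex-matched
  controls — unless an explicit age imbalance is requested via
  `case_age_shift` to study confounder leakage.
* **Baselines.** Background probes draw their mean β from a bimodal mixture
  (40% low ~ Beta(2,18), 40% high ~ Beta(18,2), 20% intermediate ~
  Beta(8,8)), mimicking the two-mode marginal distribution of array-wide
  β values. Signature probes draw mid-range baselines with enough headroom
  for the configured shift.
* **Effects.** Case effects are injected on the logit scale and
  inverse-transformed, so β stays in [0, 1] without clipping distorting the
  effect; the per-probe shift is calibrated so the noise-free case–control
  difference equals the configured `delta_beta` (0.15 by default, half of
  the probes hyper- and half hypo-methylated). A configurable fraction of
  cases carries a 50%-attenuated "milder" profile; female carriers of
  X-linked syndromes are attenuated by a factor 0.5 by default. How strong
  a "milder" profile really is has never been quantified; 0.5 is a free
  parameter, not an estimate.
* **Noise and confounding.** Probe-level Gaussian noise (sd 0.3) acts on
  the logit scale. Age (uniform 2–40 y), sex, and a 6-part Dirichlet
  (α = 8,4,3,2,2,1) cell composition act linearly on the β scale with
  slopes 0.002/year, 0.02 and 0.10 before truncation — covariate effects on
  methylation are approximately linear and that is also exactly what the
  adjustment model assumes.
* **Detection failures.** Each probe × sample measurement fails (detection
  p > 0.01) independently with probability 0.002.
* **VUS carriers.** Drawn from a configurable mixture of full-effect,
  half-effect and null profiles (defaults 1/3 each), reproducing the
  intermediate-profile phenomenon that makes VUS classification hard in
  practice. The generator records each sample's latent effect multiplier in
  the sample sheet (`true_effect`) as simulation ground truth.

What the generator does **not** emulate: probe-type chemistry and
intensity-level artifacts, batch and chip-position effects, spatially
correlated probes (every probe is conditionally independent given its
baseline), genuine biological heterogeneity among carriers, and overlap
between different syndromes' probe sets. Perfect performance on synthetic
strong-effect cohorts therefore shows that the pipeline's statistics are
correct, not that any real signature will reach those numbers; conversely
the generator's intermediate and null regimes reproduce the qualitative
failure modes (unstable sensitivity under stricter consensus, no-calls on
half-effect carriers) without claiming their real-world rates.

## Numerical choices

* Exact binomial intervals use the beta-quantile closed form, with the
  lower bound 0 at zero successes and upper bound 1 at full success.
  Displayed percentages are rounded to the nearest integer (one decimal for
  CI bounds when n ≤ 20), the way such results are printed in diagnostic
  reports; all stored values are unrounded.
* PCA is computed on mean-centered, unscaled residuals; component signs
  follow a fixed convention (largest-magnitude loading positive). An
  all-identical input is a zero-variance error, and a one-probe signature
  trivially yields a PC1 variance fraction of 1.
* Heatmap clustering uses Euclidean distance and complete linkage (the
  common default for methylation heatmaps; configurable), with rows and
  columns put in lexicographic label order before clustering so the result
  is invariant to input permutation.
* Missing β values are mean-imputed per probe for the regression fit and
  re-masked afterwards; probes missing in more than 20% of samples are
  excluded. The sample-distribution outlier rule compares each per-sample
  mean β to the cohort mean of such means at 3 sample standard deviations —
  a β-scale approximation, since the intensity statistics the original rule
  uses do not exist at β level. Note that a single outlier among n samples
  can reach at most (n−1)/√n standard deviations, so this rule only has
  power in cohorts of a dozen samples or more.
* QC runs probes-first, then samples, in a single pass (order
  configurable); fractions are not recomputed after removals.

## Problem sizes

The bundled tests and the reproduction script run cohorts of 300–1,120
probes and 35–65 samples with 100–120-probe signatures, 20-seed replication
for the stability properties, and brute-force oracle comparisons on ≤ 12
samples. These sizes keep every Monte-Carlo estimate well-conditioned (the
strong-effect regime is stable across all seeds tested) while the whole
suite runs in seconds.

## Limitations

Beyond the generator's idealisations listed above: the evaluation assumes
the β matrix is already normalised (no IDAT processing, functional
normalisation, or batch correction is attempted); epigenetic age and cell
composition are taken as given covariates, not estimated; and only the kNN
family of classifiers is provided — the evaluation framework is a
plug-in point, but comparing against SVMs or portal classifiers is out of
scope. Real-cohort sensitivities of specific published signatures depend on
patient data that cannot ship with a package; the synthetic regimes cover
the qualitative spectrum (robust / unstable / weak) instead.
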