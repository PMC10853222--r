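# episigval

Independent evaluation of DNA methylation **episignatures** — published CpG
probe sets claimed to discriminate carriers of pathogenic variants in
specific genes (mostly neurodevelopmental-disorder genes) from controls.

Published episignatures usually ship as nothing more than a probe list: the
trained classifier and most of the raw training data stay private. Before a
laboratory uses such a list to arbitrate variants of uncertain significance
(VUS), its real-world sensitivity and specificity must be measured on an
*independent* cohort. `episigval` provides a neutral, reproducible pipeline
for exactly that measurement, plus a seeded synthetic-cohort generator so
the whole pipeline is testable end to end without any patient data.

## What it computes

For a β-value matrix (probes × samples, β ∈ [0, 1]), a sample sheet with
covariates, and one or more probe lists, the package:

* applies detection-p-value QC — a probe is dropped if p > 0.01 in strictly
  more than 5% of samples; a sample is flagged above 1% failed probes or on
  an outlier methylation distribution;
* residualizes β on predicted age, sex and blood cell composition with
  per-probe OLS (β ~ 1 + age + sex + cell fractions), optionally estimating
  the coefficients on controls only;
* measures the reproducibility of each signature as the fraction of its
  probes with case–control gap |Δβ| strictly above 0.05 and 0.10;
* estimates **sensitivity**, **specificity** and **inter-syndrome
  specificity** of each signature with a multiclass consensus
  k-nearest-neighbour classifier (Euclidean distance on the signature's
  residuals; a class is called only when ≥ m of the k nearest neighbours
  agree, "m/k" from 2/2 to 5/5) embedded in a leave-one-out scheme, with
  exact Clopper–Pearson 95% confidence intervals
  (lower = Beta(α/2; x, n−x+1) quantile, upper = Beta(1−α/2; x+1, n−x));
  female carriers of X-linked genes are excluded from that gene's
  sensitivity denominator;
* classifies test samples (VUS, clinical hypotheses) against the full
  validation set at the 3/4 parametrization, flagging intermediate and
  conflicting profiles;
* summarises separability with PCA (variance explained by PC1/PC2) and
  hierarchical-clustering heatmap orderings of the signature residuals.

## Worked example

```r
library(episigval)

cfg <- cohort_config(
  syndromes = list(syndrome_spec("KabukiLike", delta_beta = 0.15),
                   syndrome_spec("SotosLike",  delta_beta = 0.15)),
  n_background_probes = 1000, n_controls = 25, n_vus_per_syndrome = 4,
  seed = 11)
cohort <- generate_cohort(cfg)

qc       <- run_qc(cohort$betas, cohort$detp)
controls <- cohort$sheet$sample_id[cohort$sheet$role == "control"]
resid    <- residualize(qc$betas, cohort$sheet, fit_samples = controls)
val      <- cohort$sheet$sample_id[cohort$sheet$role %in% c("case", "control")]

gap_table(qc$betas[, val], cohort$sheet, cohort$signatures)
#>    signature   syndrome n_probes_original n_probes_retained pct_retained
#> 1 KabukiLike KabukiLike               120               120          100
#> 2  SotosLike  SotosLike               120               120          100
#>   frac_gt_005 frac_gt_010
#> 1           1   0.9833333
#> 2           1   0.9916667

evaluate_signatures(resid[, val], cohort$sheet, cohort$signatures,
                    configs = c("2/2", "3/4", "4/4"))
#> Leave-one-out consensus-kNN performance
#>   KabukiLike 2/2  sensitivity 100% [69.2-100.0%] specificity 100% [86-100%] inter-syndrome 100% [69.2-100.0%]
#>   KabukiLike 3/4  sensitivity 100% [69.2-100.0%] specificity 100% [86-100%] inter-syndrome 100% [69.2-100.0%]
#>   ...

signature_pca(resid[, val], cohort$signatures[[1]])
#> PCA of signature 'KabukiLike': 45 samples
#>   variance explained: PC1 48.5%, PC2 5.7%

vus <- cohort$sheet$sample_id[cohort$sheet$role == "vus"]
classify_test_samples(resid[, val], cohort$sheet, resid[, vus],
                      cohort$signatures[[1]])[, c("sample_id", "call", "intermediate")]
#>           sample_id       call intermediate
#> 1 KabukiLike_VUS_01    control        FALSE
#> 2 KabukiLike_VUS_02    control        FALSE
#> 3 KabukiLike_VUS_03 KabukiLike        FALSE
#> 4 KabukiLike_VUS_04 KabukiLike        FALSE
#> ...
```

Reading the output: both synthetic signatures reproduce their configured
effect (≈ 98–99% of probes above the 0.10 gap threshold), reach 100%
sensitivity on 10 carriers (exact 95% CI [69.2–100%]) and 100% specificity
on 25 controls (CI [86–100%]) at every consensus level, and the first two
VUS carriers — simulated as benign — are correctly called `control` while
the two simulated full-effect carriers are called positive. The PC1
variance fraction (48.5%) quantifies how much of the signature's residual
variation the case/control split explains.

On weaker or intermediate-effect cohorts (smaller `delta_beta`, nonzero
`fraction_intermediate`) sensitivity degrades as the required consensus
grows and half-effect VUS carriers receive `no_call`s or flagged,
configuration-dependent calls — the qualitative failure modes that make
episignature interpretation hard in practice.

Readers for the plain-text interchange formats (`read_beta_matrix`,
`read_sample_sheet`, `load_signatures`, `read_detp_matrix`) and thin
command-line wrappers (`inst/cli/evaluate.R`, `inst/cli/classify.R`) are
included; see the vignette in `vignettes/` for the methods and the design
rationale.

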