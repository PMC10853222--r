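Package: episigval
Title: Independent Evaluation of DNA Methylation Episignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A neutral evaluation framework for published DNA-methylation
    episignatures on EPIC-array beta values. Applies detection-p-value probe
    and sample quality control, residualizes beta values on predicted age,
    sex and blood cell composition, measures case-control delta-beta
    reproducibility of published probe lists, and estimates per-signature
    sensitivity, specificity and inter-syndrome specificity with exact
    binomial confidence intervals via a multiclass consensus
    k-nearest-neighbour classifier embedded in a leave-one-out scheme.
    Variants of uncertain significance are classified against the full
    validation set. Includes PCA and hierarchical-clustering diagnostics and
    a seeded synthetic-cohort generator that emulates multi-syndrome
    case/control designs with confounding, intermediate methylation profiles
    and X-linked carrier attenuation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse
Config/testthat/edition: 3
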