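Package: stagedcad
Title: Staged Stenosis and Plaque-Burden Rules for Detecting Ischemic
    Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Registry", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating rule-based detection of ischemic coronary
    artery disease from quantitative coronary CT angiography (CTA) measures.
    Implements staged (three-zone) classification rules that combine diameter
    stenosis with plaque burden (percent atheroma volume), Youden-index and
    exhaustive grid-search cutpoint optimization, the PET perfusion
    reference-standard rule on the AHA 17-segment model, diagnostic accuracy
    metrics with Wilson confidence intervals, and paired between-model
    comparison tests (exact McNemar, generalized score for predictive values,
    and a paired test for binary-classifier AUC). A synthetic cohort
    generator emulates the selective hybrid CTA-to-PET referral protocol,
    including the verification-bias structure in which only patients with
    suspected obstructive stenosis receive the reference test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
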