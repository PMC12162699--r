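---
title: "Staged stenosis and plaque-burden rules: models, simulation and tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged stenosis and plaque-burden rules: models, simulation and tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagedcad)
```

## The problem

Coronary CT angiography (CTA) is the anatomical gatekeeper test for suspected
coronary artery disease: a diameter stenosis of at least 50% is the
conventional trigger for downstream ischemia testing. Quantitative CTA also
measures *plaque burden* — percent atheroma volume (PAV), total plaque volume
normalized to vessel volume — which carries information about ischemia beyond
the stenosis percentage. `stagedcad` implements and evaluates rule families
that combine the two:

* **binary rule** — positive iff stenosis ≥ c (conventionally c = 50);
* **gated rule** — negative below a stenosis gate; above it, positive iff
  PAV ≥ t;
* **staged (three-zone) rule** — negative below a stenosis band, positive
  above it, and inside the band positive iff PAV ≥ t.

The reference standard is myocardial ischemia on quantitative PET perfusion:
stress perfusion is abnormal when hyperaemic myocardial blood flow is
≤ 2.30 mL·min⁻¹·g⁻¹ in at least two adjacent AHA segments, the basal septum
excluded. Crucially, PET is only performed in patients referred because of a
*visually* suspected obstructive stenosis; everyone else is labelled
non-ischemic by the composite standard. That selective-verification structure
is built into the synthetic cohort generator.

## Classification rules and their conventions

All comparisons are inclusive: the stenosis band is `[lower, upper]` and the
PAV test is `pav >= pav_threshold`. The source text uses both "exceeded" and
"≥" for the same thresholds; `>=` is adopted uniformly for determinism, and
the residual ambiguity is confined to patients sitting exactly on a
threshold. A degenerate band (`upper < lower`) is interpreted as a pure
binary cutoff at `lower`, so the binary rule lives inside the same algebra
(`staged_rule(50, 0, 0)` is the conventional ≥ 50% rule). Stenosis and PAV
are floating-point percents and are never rounded before comparison.

## Diagnostic accuracy

`metrics_from_cm()` computes sensitivity, specificity, PPV, NPV and accuracy
with **Wilson score intervals**. The interval method behind published tables
of this kind is rarely stated; at the sample sizes involved Wald and Wilson
round to the same integer percents, and Wilson is preferred for its boundary
behaviour (never escapes `[0, 1]`, exact at 0/n and n/n).

For a binary classifier the ROC curve has a single interior vertex, so its
area is exactly `(Se + Sp)/2`; the package adopts this as the *definition* of
the binary AUC (the test suite verifies it against a trapezoid evaluation of
the two-point curve), with a normal-approximation interval from the two
independent binomial variances. Youden's J is `Se + Sp − 1`.

Reports round percents to integers *half away from zero* and AUC to two
decimals, matching the presentation conventions of the clinical literature
(base `round()` is half-to-even and would disagree on exact halves).

## Paired between-model tests

The published analysis compares models on the same patients but does not name
its tests. The package makes three documented choices and accepts them by
simulation (type-I error within the binomial 95% band around 0.05 at
n = 5000, 500 replicates — part of the acceptance suite) rather than by
trying to reproduce unpublished p-values:

* **Sensitivity / specificity** — exact McNemar: among reference-positives
  (resp. -negatives), the discordant pairs are tested against Binomial(m, ½),
  two-sided. Zero discordance returns p = 1 with a warning flag.
* **PPV / NPV** — the weighted generalized score statistic for paired
  predictive values (Leisenring-style): one record per (patient, test) with a
  positive (for PPV) result, a score test of equal conditional outcome
  probability with an empirical sandwich variance that respects the pairing,
  referred to χ²₁. The statistic is symmetric in the two tests.
* **AUC** — since binary AUC is `(Se + Sp)/2`, the paired difference is
  `(ΔSe + ΔSp)/2`; each Δ gets the paired-difference variance from its
  discordant counts (the DeLong paired variance specialized to binary
  scores), the strata are independent, and the ratio is referred to N(0, 1).

## Cutpoint optimization

`youden_threshold_subgroup()` restricts to a stenosis band and maximizes
Youden's J of `pav >= t` over a candidate grid (default 0.1–49.0% in 0.1%
steps), by exhaustive evaluation. Two objectives are exposed because the
source is ambiguous: `"subgroup"` (J within the band — used for the published
16.8% and 12.2% thresholds) and `"cohort"` (the candidate scored as a full
staged rule on everyone).

`grid_search_staged()` scores *every* rule `(lower, upper ≥ lower, t)` on the
grid — 99 × 100/2 × 490 = 2,425,500 rules for the default axes — by
whole-cohort J. The implementation reduces each patient to a single monotone
combined stenosis index (the count of lower bounds ≤ s plus the count of
upper bounds < s, which encodes the closed-lower/open-upper band edges) and a
PAV rank, builds one cumulative 2-D count matrix per reference class, and
reads every rule's TP/FP off four prefix lookups. All binning goes through
`findInterval()` on the grid's own values, so the fast path is *bit-identical*
to naive per-rule enumeration for arbitrary inputs, not just on-grid ones —
the test suite asserts this against a brute-force oracle on randomized toy
cohorts. Rule comparison uses the integer-scaled objective
`tp·n_ctrl − fp·n_case`, so the tie set is exact, never floating-point-fuzzy.
The full default grid at n = 20,000 runs in well under a second.

**Tie-breaking.** The grid search prefers, among maximum-J rules: higher
specificity, then the narrower band, then the lower PAV threshold. The 1-D
subgroup search prefers higher sensitivity, then the *largest* threshold;
this pair of conventions reproduces the documented behaviour of both search
styles on their reference examples. Ties are returned in full either way, so
a caller who prefers another convention can re-rank.

`refit_threshold_for_band()` is the two-step clinical procedure: take the
statistically optimal band, round it to something usable at the workstation
(e.g. 30–70%), and refit the PAV threshold inside the fixed band.

## The PET reference rule

`classify_perfusion()` implements "two adjacent segments at or below
threshold, basal septum excluded" on the AHA 17-segment polar map. The
published rule enumerates neither its segment numbers nor its adjacency;
the package maps the basal septum to segments 2 and 3 and ships a documented
hand-built adjacency (rings 1–6, 7–12, 13–16 with closure; radial neighbours
by sector, the 6:4 mid-to-apical overlap as 7–13, 8–13, 8–14, 9–14, 10–15,
11–15, 11–16, 12–16; apex 17 against 13–16). Whether the original study
counted diagonal polar-map contacts is unknowable from the text, so the
adjacency is injectable (`adjacency_from_edges()`, JSON edge lists). The
acceptance suite verifies the rule exhaustively over all 2¹⁷ below-threshold
patterns against an independent edge-logic oracle, including monotonicity:
lowering flow in any segment can never normalize an abnormal study.

## The synthetic cohort generator

No patient data accompany the source analysis, so the generator *is* the test
bed. It draws, per patient:

* **stenosis** — a zero-inflated mixture: with probability 0.40 a
  no/minimal-disease value uniform on [0, 10]%; otherwise a truncated normal
  on [0, 100]% with location 42 and scale 25. Chosen so that ~23% of patients
  exceed 50% stenosis and the group-wise medians/IQRs of the source cohort
  are bracketed.
* **PAV** — `log(PAV + 0.1) = 0.13 + 0.041·stenosis + N(0, 0.7)`, truncated
  to [0, 100]. This reproduces a monotone, heteroscedastic stenosis–PAV
  scatter (Spearman ≈ 0.8) and conditional medians near 2% (minimal disease)
  and 16% (obstructive disease), without claiming the registry's exact joint
  distribution.
* **NCPV/CPV** — a Beta(1.5, 4.5) calcified fraction of PAV; the split's
  joint distribution is unspecified in the source, and nothing downstream
  uses it beyond schema completeness.
* **latent ischemia** — logistic in stenosis and PAV:
  `logit p = −5.1 + 0.06·stenosis + 0.11·PAV`. The PAV coefficient matches
  the published adjusted odds ratio of 1.12 per 1% PAV; the intercept was
  calibrated once (100k-patient run) to the stated 17% prevalence and then
  frozen. Alternatively, **planted-rule mode** makes the latent label a noisy
  copy of a chosen staged rule (independent flip probability, default 0.1) —
  the recoverability test bed.
* **referral and the composite label** — a *visual* stenosis reading,
  `stenosis + 12 + N(0, 7)` truncated to [0, 100], decides PET referral at
  the 50% cutoff; `ischemia = latent & referred`. The +12% bias is a modelling
  choice, not a published value: zero-mean misreading noise cannot reconcile
  the stated 36% referral rate with only 23% quantitatively obstructive
  patients, and the source itself attributes the gap to visual
  overestimation.

The generator consumes a fixed number of uniforms per record from a single
seeded stream (all non-uniform draws are inverse-CDF transforms), so record i
is identical for every cohort size ≥ i and cohorts are exactly reproducible.

**What a green test does and does not establish.** The synthetic world has
the *structure* of the registry protocol — selective verification, correlated
stenosis/PAV, a plaque-burden signal beyond stenosis — and its headline rates;
it does not have the registry's joint distribution, its per-vessel anatomy,
its measurement error, or its clinical covariates. Green acceptance tests
establish that the machinery is correct (exact fixture reproduction, oracle
equivalence, calibrated tests, recoverable planted truth), not that the
published optimal band (31–63% + PAV 7.7%) re-emerges: that number is a
property of the unavailable patient data. Accordingly, the grid optimum on
synthetic cohorts lands in the same neighbourhood but is not asserted
anywhere.

Note also what the recovery experiment shows about verification bias: a
planted rule is recovered from the *latent* labels; against the *composite*
labels the searchable lower band edge is truncated toward the referral
cutoff, because unreferred in-band patients are forced negative. That is the
bias the protocol imposes on any real re-analysis, made visible by
construction.

## Numerical conventions

* Percent rounding half away from zero; AUC to 2 decimals (reports only —
  comparisons never round).
* Exact-rational tie detection in both searches (integer scaled objective).
* Wilson bounds clamped exactly to 0 and 1 at degenerate counts.
* Degenerate comparison inputs: identical classifications give p = 1 (flagged
  where informative); undefined metrics (zero denominators) are `NA` and
  named in `$undefined` rather than poisoning the rest of the report.
* The composite-label invariant (`ischemia ⇒ pet_performed`) is enforced at
  CSV ingestion, not just at generation.

## Known limitations

* The paired tests are asymptotic except McNemar; very sparse discordance
  will make the score and AUC tests conservative.
* The generator models no clinical covariates and no per-lesion structure;
  NCPV/CPV are decorative for the implemented rules (PAV is the only plaque
  measure any rule consumes).
* Published p-values and the headline grid optimum are out of reach by
  design (no patient-level data); the package reproduces the published
  *metric table* exactly from the packaged confusion matrices and validates
  everything else by construction and simulation.
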