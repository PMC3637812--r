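---
title: "A latent class reference standard for screening colonoscopy algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latent class reference standard for screening colonoscopy algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenlca)
```

## The scientific problem

Administrative claims record *that* a colonoscopy happened, not *why*.
Whether an exam was a screening exam (asymptomatic patient, early
detection) or a diagnostic/surveillance exam must be inferred, and there
is no gold standard to validate the inference against: endoscopists,
patients and charts all disagree with one another at non-trivial rates.
This package treats the true indication as a **latent class** and builds
the entire validation chain on top of it: reference-standard
construction, predictor extraction from claims, model-based classifiers,
an expert comparator rule, and accuracy scoring.

## The latent class model

For each exam let `D = 1` denote a true screening indication, with
prevalence `π = P(D = 1)`. Three binary indicators are observed: the
endoscopist's stated indication (`T1`) and two patient-questionnaire
derivations (`T2`, `T3`). Each responds imperfectly, with sensitivity
`S_j` and specificity `C_j`. Under conditional independence given `D`,
the 8 response patterns follow the two-component mixture implemented in
`cell_probabilities()`. Three indicators with two classes give 7 degrees
of freedom for 7 parameters, the classic boundary case for
identifiability without a gold standard; informative priors stabilize
what the likelihood leaves flat.

**Priors.** `lca_priors()` defaults to the elicited study priors:
Beta(10.67, 1.06) for both `S_1` and `C_1` — the assumption that the
endoscopist reports the true indication at least 70% of the time; its
exact mass on [0.70, 1] is 97.5% (`prior_coverage(10.67, 1.06, 0.7, 1)`)
— flat Beta(1, 1) for the patient indicators, and Beta(6, 7.6) for
prevalence (95% mass on [0.20, 0.70], mean 0.441).

**Sampler.** `gibbs_sample()` uses data augmentation: given parameters,
each pattern count is split into latent screening/non-screening counts
by a binomial draw; given the split, all parameters have conjugate beta
updates. No proposal tuning is needed and one sweep costs O(8)
regardless of cohort size (the pattern counts are sufficient), which is
why the test suite can afford parameter-recovery checks at n = 100,000.
Defaults: 3 chains × 20,000 iterations, 5,000 burn-in, thinning 5,
convergence monitored by split-chain potential scale reduction on `π`
(warning threshold 1.05).

**Identifiability.** The likelihood is exactly invariant under
`(π, S, C) → (1 − π, 1 − C, 1 − S)` — relabeling the classes. The
sampler breaks the symmetry by rejection: every `(S_j, C_j)` draw must
satisfy `S_j + C_j > 1` (each indicator is better than inverted
guessing). This is a substantive assumption, reasonable for indication
questionnaires.

**Dependence variant.** Both patient indications derive from one
interview, so their errors may correlate. With `dependence = TRUE` the
within-class joint of `(T2, T3)` is a free 2×2 table: joint cell
probability = product of marginals + covariance, the same
parameterization the synthetic generator uses (one definition shared by
estimator and generator). The sampler updates the within-class cell
probabilities with conjugate Dirichlet(1,1,1,1) draws — the flat
extension of the flat marginal priors — and reports the implied
covariances. With zero covariance the cell probabilities reduce
*exactly* to the independence model. The dependence posterior mixes more
slowly; the default chain settings are chosen with that model in mind,
and short exploratory chains can leave borderline patterns on the wrong
side of the cut-off.

**From posterior to reference standard.** `pattern_posterior()` computes
`P(D = 1 | pattern)` per retained draw and summarizes each pattern by the
posterior *median*, dichotomized at 50%; `latent_reference()` transfers
the pattern labels to patients. A median of exactly 0.5 labels screening
(the cut-off is read as inclusive; documented tie rule, exercised in the
tests). An alternative — plugging per-parameter posterior medians into
the probability formula — gives the same labels away from the boundary;
the per-pattern median is reported because it is the direct posterior
summary of the quantity being thresholded.

Typically six of the eight patterns are decisively labeled; the two
patterns where the endoscopist disagrees with both patient indications
(`100`, `011`) sit near the cut-off, and which side they fall on drives
essentially all seed-to-seed variability in the screening count and in
the kappa against the endoscopist indication.

## Claims predictors

`extract_features()` reduces claims to 14 binary flags over per-category
lookback windows anchored at the index colonoscopy: 4 years for prior
procedures (colonoscopy, polypectomy, sigmoidoscopy, DCBE), 1 year for
symptoms (rectal bleeding, diarrhea, vomiting, weight loss, anemia),
5 years for conditions (CRC, polyps, IBD), large-bowel hospitalizations
and large-bowel surgeries. Numerical choices:

* **Half-open windows** `[index − lookback, index)`: a same-day code is
  taken to be the index exam itself, not history. Whether the original
  study excluded the index exam's own billing record is not stated; this
  convention is a package decision.
* **Fixed day counts** (1 y = 365 d, 4 y = 1460 d, 5 y = 1825 d),
  ignoring leap days: reproducibility over calendar fidelity;
  configurable in the dictionary.
* The concrete provincial code inventories are not public; the bundled
  dictionary ships clearly synthetic placeholder codes (`SYN-` prefix)
  and is meant to be edited for real data.

## Classifiers and scoring

**Logistic regression.** `fit_logistic()` maximizes the Bernoulli
likelihood by iteratively reweighted least squares after aggregating
duplicate covariate patterns into binomial groups (identical fit, much
faster). `best_subset_by_bic()` enumerates all `2^p` subsets of up to 20
candidates — exhaustive search is deterministic, feasible for the 16
candidates used here, and avoids the path dependence of stepwise
selection. Ties in BIC break toward fewer variables, then candidate
order. Age enters linearly in years (no transformation stated or
assumed). Separated fits are capped at |coef| ≤ 15 and flagged
non-converged rather than silently reported.

**AUC.** `auc()` is the Mann–Whitney concordance probability with ties
counted ½ and a DeLong 95% CI (via pROC); the test suite verifies it
against brute-force pair enumeration on every fixture up to 200
patients.

**Recursive partitioning.** `fit_tree()` grows a binary Gini tree over
the 14 flags (age and sex excluded by default, matching the published
tree's variable set; includable via `variables`). Stopping: pure node,
fewer than `min_node = 20` rows, or no strictly positive impurity
decrease. Leaf ties label screening; split ties take the earlier
variable in the configured order; a variable is never reused on a path
(binary splits leave it no information). The default tree is
**unpruned** — fully deterministic, and the study's own sensitivity
analysis found pruning did not change conclusions — with cost-complexity
pruning under 10-fold CV available via `prune = TRUE`. The splitting
engine is deliberately written in-package so these tie-breaks are pinned
down; rpart serves as an independent cross-check in the tests.

**Expert rule.** `el_serag_classify()` labels an exam screening iff no
claim matches any of 28 disqualifying symptom/condition categories in
window and no colonoscopy procedure code appears in the prior 4 years.
The original 28-code ICD-9 inventory is not reproducible from public
sources, so the bundled configuration lists 28 named categories (a
superset of the predictor dictionary's symptom/condition categories)
with synthetic codes, and the diagnosis lookback defaults to the same 4
years as the colonoscopy clause (the original window is unstated). The
rule is monotone by construction: adding claims can only remove
screening labels.

**Accuracy.** `accuracy_report()` returns sensitivity, specificity, PPV
and NPV with Wald 95% CIs — the method that reproduces the published
intervals from back-derived confusion counts (Wilson intervals are
available by option). Zero-denominator metrics are reported as
undefined, never as 0. `cohens_kappa()` uses the Fleiss–Cohen–Everitt
asymptotic variance.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: ~1,230 patients aged
50–75 (truncated-normal ages, mean 60.1, SD 6.9; 48.5% male), index
dates in January–March 2007, screening prevalence 0.46, and indicator
sensitivities/specificities (0.93, 0.93), (0.87, 0.80), (0.72, 0.89)
chosen once so the indicator marginals land on the observed 46.8%,
51.0% and 38.9% screening fractions. Claims flags are drawn per latent
class with conditional probabilities solved (once, frozen in the
bundled YAML) from two constraints per category: the observed marginal
frequency, and a screening-vs-non-screening odds ratio matching the
reported direction (all below 1) — the published estimates where
available, 0.5 where not. One claim is emitted per flag, dated
uniformly inside the category's window, so the extractor provably
recovers the injected flags (round-trip tested). Indicators 2 and 3 can
be generated with within-class covariance using the estimator's own
parameterization.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: multiple/repeat claims per episode, coding
error and province-specific code semantics, correlation *between*
predictor categories beyond what the latent class induces, referral
wait-times, and the realistic density of disqualifying diagnosis codes.
That last point matters for the expert rule: with only the injected
categories present, far fewer synthetic patients are disqualified than
in real claims, so the rule labels ~50% of synthetic exams screening
versus 32% in the study, with correspondingly higher sensitivity and
lower specificity. Comparisons *between* algorithms on synthetic data
are informative; absolute agreement with the published expert-rule row
is not expected.

## Problem sizes and numerical checks

The test suite works at three scales, chosen to make Monte-Carlo error
negligible relative to each tolerance: n = 100,000 simulated draws for
closed-form marginal and parameter-recovery checks (posterior medians
within 0.02 of generating values), the study-sized n = 1,230 for
end-to-end behaviour, and tiny fixtures (10 counts, ≤ 200 patients) for
exact oracles. The Gibbs sampler is validated against an independent
grid/analytic integration of the posterior on a two-cell dataset —
binomial expansion makes every term a product of analytic beta moments
and 2-D truncated-prior integrals evaluated by midpoint quadrature —
and against the exact prior when fitted to empty data. The full
pipeline at n = 1,230 (two exhaustive 2^16 subset searches included)
runs in about two minutes on one CPU.

## Known limitations

* Three indicators, two classes only; no covariate-dependent prevalence.
* The latent standard inherits the endoscopist prior: with flat patient
  priors, labels are driven mainly by `T1`, so kappa against the
  endoscopist indication is optimistic relative to truth.
* Exhaustive subset search is exponential; 20 candidates is the hard
  ceiling.
* Synthetic claims realism as discussed above.
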