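---
title: "Modelling metformin response in PCOS: connectivity maps, evolutionary feature selection and drop-out risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metformin response in PCOS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Metformin improves ovulatory and metabolic function in a subset of women
with polycystic ovary syndrome (PCOS), but response is inconsistent and
discontinuation is common. This package re-implements, as a tested and
reusable pipeline, an analysis strategy for finding baseline predictors of
response: derived endocrine indices and response labelling, median
dichotomization into paired HIGH/LOW nodes, auto-contractive map (Auto-CM)
associative networks filtered by a minimum spanning tree into semantic
connectivity maps (SCMs), evolutionary feature selection scored by a
backpropagation classifier (the TWIST scheme), and logistic modelling of
drop-out risk. Because the original patient-level data are not public, the
package ships a synthetic cohort generator that emulates the statistical
structure the analysis assumes; every downstream stage is validated by its
ability to recover what the generator plants.

# Cohort model and derived indices

A cohort is a long table, one row per patient-visit (`m0`, `m6`, `m12`),
with the anthropometric, metabolic, endocrine and ultrasonographic
variables of a standard PCOS work-up. Derived indices:

* BMI = weight (kg) / height (m)^2;
* WHR = waist / hip;
* FAI (%) = total testosterone (ng/mL) x 347 / SHBG (nmol/L), with
  FAI >= 6% defining biochemical hyperandrogenemia;
* HOMA-IR = glucose (mg/dL) x 0.05551 x insulin (uU/mL) / 22.5;
* LH/FSH ratio.

Missing inputs propagate to `NA` for the index — never to zero — and any
label depending on a missing index is undefined rather than false.

## Outcomes and study-flow accounting

The two primary outcomes are a BMI reduction of at least 1 kg/m^2 in
overweight/obese women (BMI >= 25 at baseline; the WHO overweight
threshold, chosen because the source protocol does not print its own
cutoff) and an FAI decrease of at least 1 percentage point in
hyperandrogenemic women (FAI >= 6 at baseline). The m6 label compares m6
with m0; the m12 label measures *further* improvement, m12 against m6.

Response *rates* are intention-to-treat. The m6 denominator is everyone
eligible at baseline; a woman without an m6 assessment counts as a
non-responder. For the m12 "further improvement" rate the denominator is
the women assessed at m6 whose m6 value still meets the eligibility
criterion (BMI >= 25 at m6, or FAI >= 6 at m6), again counting missing m12
as non-response. This re-assessed-eligibility rule was a genuinely open
design point: the alternative — requiring an m12 measurement in the
denominator — is arithmetically incompatible with the flow counts this
pipeline is designed to reproduce (more women belong in the m12 BMI
denominator than have an m12 visit), whereas the rule implemented here is
consistent with them. `synthetic_flowchart_cohort()` encodes that flow as
a deterministic fixture, and `flow_report()` reproduces every published
fraction from it exactly (52.4% = 54/103, 50.6% = 45/89, 30.6% = 22/72,
47.1% = 24/51, 79.4% = 108/136, 75.9% = 82/108, 29.6% = 32/108,
8.3% = 9/108).

Percentages are printed to one decimal using round-half-even (R's
`round()`). A responder comparison uses a 1e-9 epsilon so that a drop of
exactly the threshold survives floating-point round-trips through the
weight/height parametrisation.

# The synthetic cohort generator

`cohort_config()` fixes the study conditions; its defaults are not tuning
knobs.

**Marginals.** Each baseline variable is matched to the published
mean/SD (and median, where stated) of the enrolled population. Skewed
positive variables — insulin, triglycerides, testosterone, SHBG, DHEAS and
the LH/FSH ratio — use log-normal marginals; when a median target is
stated the log-normal matches the median exactly and the mean through its
shape parameter (the SD is then implied), which puts derived medians such
as HOMA-IR's on their published values. Symmetric variables use truncated
Gaussians whose truncated mean and SD are matched numerically
(Nelder-Mead on the closed-form truncated moments), so bounded scores
like Ferriman-Gallwey still recover their target means. Counts are
rounded and clamped to their physical ranges (menses 0-6, FG 0-36).
Height is drawn N(1.63, 0.06) m — never reported in the source protocol —
so that weight/height^2 reproduces the printed BMI scale; hip
circumference (N(110, 10) cm) is likewise an invented nuisance marginal
that only serves to realise the WHR.

**Dependence.** A Gaussian copula imposes a small set of clinically
plausible correlations: weight-insulin 0.4, glucose-insulin 0.3,
testosterone-SHBG -0.35, menses-testosterone -0.3. These are synthetic
choices made once to render the planted structure discoverable; they are
fully overridable. Correlations involving FAI itself are induced through
its inputs, since FAI is a derived ratio, not a drawn marginal. An
infeasible correlation matrix (not positive definite) is rejected with
the offending pairs named.

**Planted response.** Responder status is drawn from logistic models on
dichotomized baseline indicators, thresholded at the published map
captions (CYCL <= 2 menses/6 months, FAI > 9, FG > 12, HOMA > 4,
TRIGL > 110, GLIC <= 90, DHEA <= 270, BMI > 32). The BMI-response
coefficients decrease over oligo-amenorrhea (1.6), hyperandrogenemia
(1.2), hirsutism (0.8) and insulin resistance (0.5) — the priority
ordering the maps should recover — with the intercept set for a marginal
response rate near one half. BMI responders receive a planted drop of at
least 1 kg/m^2; FAI responders a drop of at least 1 percentage point,
realised as an SHBG rise with the consistent testosterone value, so the
treatment direction (T falls, SHBG rises) is preserved. Other variables
drift with the direction observed under treatment, at half magnitude in
the second interval.

**Drop-out.** A logistic model in the indicator `baseline T < 0.90
ng/mL` with planted odds ratio 6.5 (the study-scale estimate this
emulates); drop-outs are truncated at their interval, reasons follow the
published multinomial (14:21:11), and pregnancies remove ~4.5% of
on-treatment women per interval.

**Reproducibility.** Every patient draws from a counter-keyed substream
of the run seed, so patient `i` is identical whatever the cohort size
(n-invariant prefixes), and regeneration is exact.

**What it does not emulate:** assay error, visit-time jitter, the exact
printed m6/m12 column means (those mix completers with future drop-outs
in the source tables), or any real-data feature beyond the moments,
correlations and planted effects above. Passing recovery tests therefore
demonstrates that the pipeline can find structure of the planted kind and
size — not that it would find the same structure in the original cohort.

# Median dichotomization

`compute_cutoffs()` takes per-variable sample medians (mean of central
order statistics for even n); `dichotomize_matrix()` emits two
complementary nodes per variable — `*_HIGH` strictly above the cutoff,
`*_LOW` at or below — plus the outcome pole pair
`RESPONDER`/`NON_RESPONDER`. Ties go LOW, consistent with every published
HIGH caption being a strict ">". Both polarities are materialised because
both appear as separate nodes in the maps. Cutoffs are computed on the
full baseline cohort by default (the published captions coincide with the
full-cohort medians); since the function accepts any baseline subset,
computing them on an outcome-eligible subset is a one-line variant.
Constant variables keep their value as cutoff and are flagged degenerate;
all-missing variables are excluded with a warning.

# Auto-contractive maps and the SCM

For a record `x` with entries in [0,1]:

* hidden: `h_i = x_i (1 - v_i/C)`
* net: `net_j = sum_i h_i (1 - W_ij/C)`
* output: `out_j = h_j (1 - net_j/C)`

with contraction updates `dv_i = x_i (x_i - h_i)(1 - v_i/C)` and
`dW_ij = h_i (h_j - out_j)(1 - W_ij/C)`. The W rule credits the
contraction of the receiving node to each sender in proportion to its own
activation; it is non-zero only when both nodes fire together, which is
what makes the frozen W a many-to-many association measure (duplicated
columns attract the maximal off-diagonal weight; closeness `C - W`
correlates positively with co-occurrence).

Numerical choices, each of which matters:

* **Initialization** is a uniform small positive constant (`C * 1e-3`),
  not zero: zero is a fixed point of the `dv` rule, so nothing would
  train from the origin. A constant (rather than random) start keeps
  training fully deterministic.
* **Batch updates**: deltas are averaged over all records of an epoch and
  applied once. This makes training invariant to record order (verified
  to 1e-12; the residual is floating-point summation order) and the step
  size independent of n.
* **C defaults to the number of nodes**, the usual convention; with
  `C = N` the output contraction `1 - net_j/C` cannot go negative for
  binary inputs.
* **Convergence** is declared when the epoch energy
  `sum(|dv|) + sum(|dW|)` falls below `tol` (default 1e-6); the monotone
  weights `v` approach `C`, shutting the hidden layer down, so the energy
  is non-increasing after its burn-in peak. The epoch budget (default
  10000) matters because convergence time grows with `C` and with the
  rarity of the least active node; an unconverged model carries a warning
  flag rather than an error.

Distances are `d_ij = C - (W_ij + W_ji)/2`, zero on the diagonal; larger
trained weights mean smaller distances. The minimum spanning tree — the
"mathematical filter" that turns the dense distance matrix into a map —
is computed on the *unrescaled* distances (the min-max rescaled copy is
cosmetic, for layout only) by Kruskal's algorithm with a deterministic
lexicographic tie-break, and is checked in the test suite against
exhaustive enumeration of spanning trees and against an independent
implementation. Pole priorities order nodes by tree hops from the
`RESPONDER` pole, ties broken by summed path weight, then label; this is
the "separation grade" reading of the map.

On 2000-patient synthetic cohorts the BMI-response map recovers the
planted priority ordering — oligo-amenorrhea (CYCL LOW) closest to the
responder pole, ahead of hirsutism (FG HIGH) — in 10 of 10 seeded
replicates in the acceptance suite.

# TWIST-style selection and the backprop classifier

The selection layer co-evolves a feature mask and a balanced A/B record
split, scored by ab/ba validation: train on A, test on B; train on B,
test on A; average. The engine is a standard elitist genetic algorithm —
tournament selection of size 2, uniform crossover of mask and split,
bit-flip mutation, split repaired to 40-60% balance with both outcome
classes on both sides — which approximates the proprietary evolutionary
system of the original software; its internals are unpublished, so the
validated surface is feature recovery on planted data, not equivalence.
A split leaving a class absent from either half scores zero. The elite
fitness track is non-decreasing by construction.

The fitness classifier is a single-hidden-layer network trained by
full-batch gradient descent on the cross-entropy, with either
logistic-sigmoid or sine hidden activation (the two shipped presets are
backprop with 4 hidden units and the sine net with 8). Features are
standardised internally; initialization is seeded uniform, so training is
deterministic. ROC AUC uses the rank (Mann-Whitney) formulation with
half-credit ties, and equals the normalised U statistic of the inference
module by construction.

On the planted benchmark (600 records, 4 informative features with
logistic coefficient 1.5 each, 8 noise features; GA population 20, 15
generations; 60-epoch networks), at least 3 of the 4 informative features
are selected in at least 8 of 10 seeded runs.

# Classical inference

* **Mann-Whitney**: exact p by exhaustive enumeration of group
  assignments when n1 + n2 <= 10 (valid under ties); otherwise the
  tie-corrected normal approximation with continuity correction (the
  correction is what keeps exact and approximate p within 0.02 of each
  other at n1 = n2 = 8). Two-sided throughout.
* **Friedman**: within-subject rank ANOVA with the standard tie
  correction (via `stats::friedman.test`); an all-constant matrix returns
  statistic 0 by convention.
* **Logistic regression**: maximum likelihood by IRLS (`stats::glm`),
  odds ratios with Wald 95% intervals — Wald, not profile likelihood,
  because the interval shapes this analysis reproduces are characteristic
  of Wald intervals on small samples. Constant covariates, collinearity
  and perfect separation are reported as errors naming the covariate.
* **2x2 odds ratio**: ad/bc with a Woolf interval; the Haldane-Anscombe
  0.5 correction is added to every cell when any cell is zero; a zero row
  or column is an error (undefined OR).
* **Pearson/point-biserial correlation** via `stats::cor.test`.
* No multiplicity correction is applied anywhere, matching the p < 0.05
  convention of the protocol this pipeline follows.

The completers-versus-discontinuers comparison supports two groupings —
everyone assessed at m6 versus first-interval drop-outs, or 12-month
completers versus all discontinuers — because the source presentation is
ambiguous about which grouping produced its table; both are one flag
apart, and group sizes always come from record status, never from
hard-coded counts.

# Orchestration and problem sizes

`run_pipeline(run_config(...))` chains generate-or-ingest, derivation,
labelling, flow accounting, dichotomization, both SCMs (BMI at m6, FAI at
m12, where each map polarises in this analysis), TWIST and the drop-out
statistics, writing JSON/CSV/GraphML artefacts plus a manifest (seed,
config hash, versions). Identical config and seed give byte-identical
outputs. SCM, TWIST and drop-out stages skip with a warning below 20
analysable patients — half the smallest analysis set this design is meant
for — rather than fitting models that cannot be meaningful.

Validation scales, chosen once as the package's own conditions: marginal
recovery at n = 4000-5000; SCM priority recovery on 10 cohorts of
n = 2000; drop-out odds-ratio coverage over 50 replicates of n = 2000
(the planted 6.5 must fall inside the fitted Wald interval in at least
90%); TWIST recovery over 10 runs of n = 600; Wald type-I calibration
over 1000 null replicates; the analysis drivers run the study-scale
n = 108 cohort plus a 2000-patient cohort for the recovery experiments.

# Known limitations

* The evolutionary engine and the Auto-CM equations follow published
  conventions, not the proprietary implementations; agreement is at the
  level of stated invariants and recovery behaviour.
* Map-level "accuracy" figures reported for SCMs elsewhere have no
  defined metric for a spanning tree and are not implemented; predictive
  accuracy lives in the TWIST/classifier layer.
* The generator does not target the printed follow-up column means, so
  numeric agreement with follow-up tables is out of scope by design.
* Real-cohort quantities (group p-values, multivariate odds ratios, ROC
  curves) cannot be reproduced without the original data; the pipeline
  demonstrates recovery of planted analogues instead.
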