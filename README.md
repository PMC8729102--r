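# pcosmet

Predictors of metformin response in polycystic ovary syndrome (PCOS),
re-implemented as a tested R pipeline: derived endocrine indices and
outcome labelling, median dichotomization, auto-contractive map (Auto-CM)
semantic connectivity maps with minimum-spanning-tree filtering,
TWIST-style evolutionary feature selection with a backpropagation
classifier, and logistic drop-out modelling — exercised on a synthetic
cohort generator that stands in for the (non-public) study data.

It is written for biostatisticians and reproductive-endocrinology
researchers who want to apply, audit or extend this class of
connectivity-map analysis on longitudinal clinical cohorts.

## The methods in brief

**Indices.** FAI (%) = T (ng/mL) × 347 / SHBG (nmol/L), hyperandrogenemia
at FAI ≥ 6; HOMA-IR = glucose (mg/dL) × 0.05551 × insulin (µU/mL) / 22.5;
BMI = weight/height²; WHR = waist/hip. Response = BMI drop ≥ 1 kg/m² in
overweight/obese women, FAI drop ≥ 1 point in hyperandrogenemic women,
per 6-month interval.

**Auto-CM.** Records `x ∈ [0,1]^N` pass through a three-layer contractive
system — `h_i = x_i(1 − v_i/C)`, `net_j = Σ_i h_i(1 − W_ij/C)`,
`out_j = h_j(1 − net_j/C)` — with updates
`Δv_i = x_i(x_i − h_i)(1 − v_i/C)` and
`ΔW_ij = h_i(h_j − out_j)(1 − W_ij/C)`. The monotone weights contract to
`C`; the frozen matrix `W` ranks co-occurring node pairs highest.
Distances `d_ij = C − (W_ij + W_ji)/2` are filtered by a minimum spanning
tree into a semantic connectivity map; predictors are prioritised by
tree-path separation from the `RESPONDER` pole.

**TWIST.** A genetic algorithm co-evolves a feature mask and a balanced
A/B split, scored by the ab/ba-validated accuracy of a single-hidden-layer
backprop network (sigmoid or sine activation); ROC AUC uses the
Mann-Whitney rank formulation.

**Drop-out.** Logistic regression with Wald odds-ratio intervals, 2×2
risk tables (Woolf CI, Haldane correction), Mann-Whitney group
comparisons and point-biserial correlation.

## Worked example

The numbered drivers under `analysis/` run the whole study in order
(`01_simulate.R` … `05_dropout.R`), writing their tables under
`results/`. The flow accounting on the deterministic reconstruction of
the study flow chart prints:

```
Study flow report
  enrolled 108, assessed m6 82, assessed m12 53
  eligibility                      108 / 136  (79.4%)
  retention_m6                      82 / 108  (75.9%)
  non_side_effect_discontinuation   32 / 108  (29.6%)
  pregnancy                          9 / 108  (8.3%)
  bmi_response_m6                   54 / 103  (52.4%)
  fai_response_m6                   45 /  89  (50.6%)
  bmi_further_response_m12          22 /  72  (30.6%)
  fai_further_response_m12          24 /  51  (47.1%)
```

i.e. 52.4% of overweight/obese women respond in BMI at 6 months and
50.6% of hyperandrogenemic women in FAI, with further improvement in
30.6% and 47.1% over the second interval.

On a 2000-patient synthetic cohort (`analysis/03_scm.R`), the
BMI-response connectivity map places the planted predictors in the
planted order — oligo-amenorrhea first:

```
nodes closest to the RESPONDER pole:
      node hops path_weight
1 CYCL_LOW    1         9.2
2  FG_HIGH    1        12.5
```

and the drop-out analysis (`analysis/05_dropout.R`) recovers the planted
6.5-fold risk of discontinuation for baseline testosterone below
0.90 ng/mL:

```
low baseline T (< 0.90 ng/mL) drop-out odds ratio: 6.26 (95% CI 4.58-8.56), p = 1.36e-30
correlation of baseline T with drop-out: r = -0.215, p = 4.26e-21
```

A single call runs everything end to end on a fresh synthetic cohort:

```r
library(pcosmet)
out <- run_pipeline(run_config(generator = cohort_config(n = 108), seed = 1))
list.files(out)  # flow_report.json, cutoffs.csv, scm_bmi.graphml, ...
```

## Layout

- `R/` — the package: cohort model (`as_cohort`, `derive_indices`,
  `label_outcomes`, `flow_report`), synthetic generator
  (`cohort_config`, `generate_cohort`), dichotomization
  (`compute_cutoffs`, `dichotomize_matrix`), Auto-CM/SCM
  (`train_autocm`, `weights_to_distances`, `minimum_spanning_tree`,
  `build_scm`), TWIST (`twist_run`, `train_mlp`, `roc_auc`), inference
  (`mann_whitney`, `friedman`, `logistic_fit`, `two_by_two_or`,
  `pearson_r`) and orchestration (`run_pipeline`).
- `analysis/` — numbered narrative drivers.
- `vignettes/metformin-response-pipeline.Rmd` — the methods vignette:
  model assumptions, parameter defaults, what the generator does and does
  not emulate, numerical choices and limitations.
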