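# patientsim

Learning-based patient similarity for heterogeneous electronic medical
record (EMR) data, with a personalized kNN disease-prediction harness.

EMR data mixes types that share no natural distance: ages, binary flags,
hierarchical ICD-10 comorbidity codes, sets of abnormal laboratory tests and
free-text report phrases. `patientsim` is for biostatisticians and clinical
data scientists who want a *learned*, rather than hand-weighted, similarity
between patients built from such data. The pipeline:

1. **Feature-level similarity.** Every unordered patient pair gets a
   12-component vector: age ratio `min/max`; agreement indicators for sex,
   drug-allergy history, admission source and five decisive report phrases;
   an information-content (IC) similarity for comorbidities,
   `IC(c1, c2) = -log p(NCA)` where the NCA is the longest common prefix of
   the two ICD-10 codes in a cohort-wide fragment corpus (rare shared
   families count for more than common ones), averaged over all code cross
   pairs and min-max normalized; and Jaccard similarities for the
   abnormal-lab and report-phrase sets.
2. **Metric learning.** Expert similarity scores for all pairs among a small
   patient sample are cut at their tertiles into must-link / general-link /
   cannot-link constraints. A Mahalanobis metric
   `d(v_p, v_q) = sqrt((v_p - v_q)' C (v_p - v_q))`, `C = A'A` PSD, is
   learned by minimizing the trace quotient
   `tr(A S_w A') / tr(A S_b A')` (within- over between-class scatter of the
   labeled pair vectors) with a decomposed Newton iteration over
   row-orthonormal projections `A`.
3. **Snowballing propagation.** With `C` fixed, batches of unlabeled pairs
   (0.15% of the unlabeled pool per round by default) copy the score of
   their nearest labeled pair and join the labeled set, until every pair is
   scored.
4. **Prediction.** Leave-one-out personalized kNN (k = 10) over four
   combinations of training-sample selection and neighbour metric
   (R+L, R+E, L+E, E+L; R = random, L = learned similarity, E = Euclidean
   distance on a flat 131-feature representation), reporting micro-averaged
   AUC, F1-score and cross-entropy loss.

Because real EMR cohorts and expert scores cannot be shipped, the package
includes a first-class synthetic cohort generator (four latent liver
conditions with class-conditional demographics, comorbidity families, labs
and report phrases) and a configurable expert-score oracle, so the entire
pipeline is reproducible end to end. See the methods vignette
(`vignettes/patient-similarity-methods.Rmd`) for the model, assumptions and
design decisions.

## Worked example

```r
library(patientsim)

## synthetic cohort of 100 patients, outcome-defining codes excluded
cfg    <- cohort_config(n_patients = 100, seed = 7)
cohort <- exclude_outcome_codes(generate_cohort(cfg))
cohort
#> EMR cohort: 100 patients
#>   classes: cancer=14, hemangioma=16, NAFLD=34, normal=36

## pair similarity vectors, expert scores for 30 patients, fit
schema <- build_text_schema(cohort, independent = independent_phrases())
pairs  <- pairwise_similarity_table(cohort, schema = schema)
set.seed(7)
expert_ids <- sort(sample(cohort_ids(cohort), 30))
expert <- expert_label_pairs(pairs, expert_ids,
                             oracle_config(noise_sd = 0.05, seed = 7))
fit <- patient_similarity(cohort, expert, schema = schema)
fit
#> Learned patient similarity
#>   cohort: 100 patients, 4950 pairs (435 expert-labeled, 4515 propagated)
#>   metric: d = 12, rank r = 2, trace quotient lambda* = 0.1966
#>   propagation: 645 snowball rounds
```

All `choose(30, 2) = 435` pairs among the expert's patients are labeled; the
remaining 4515 pairs received propagated scores. The achieved trace quotient
`lambda* = 0.197` means the learned projection makes within-constraint
scatter about five times smaller than between-constraint scatter.
`summary(fit)` shows where the metric puts its mass — here 84% of the
diagonal lands on the three set-valued components the score oracle actually
weights (comorbidity 0.175, labs 0.491, text set 0.172):

```r
summary(fit)
#>   metric diagonal mass by component:
#>     age 0.014  sex 0.018  drug_allergy 0.019  admission_source 0.026
#>     text_1..5 ~0.01-0.02  comorbidity 0.175  labs 0.491  text_set 0.172
```

`coef(fit)` returns `C`, `similarity_matrix(fit)` the patient-by-patient
scores, `plot(fit)` an image of `|C|`. Prediction:

```r
predict(fit, "R+L", M_percent = 100, k = 10, seed = 1)
#> kNN prediction run (R+L, M = 100%, k = 10): n = 100
#>   micro-AUC 0.927, F1 0.760, CE loss 0.993

predict(fit, "R+E", M_percent = 100, k = 10, seed = 1)
#> kNN prediction run (R+E, M = 100%, k = 10): n = 100
#>   micro-AUC 0.895, F1 0.710, CE loss 0.768
```

Choosing neighbours by the learned similarity (R+L) beats Euclidean
neighbours (R+E) on micro-AUC here because the cohort's class signal lives
partly in the hierarchical comorbidity codes and phrase sets that the flat
131-feature Euclidean view cannot see well.

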