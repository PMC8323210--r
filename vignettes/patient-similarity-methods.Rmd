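---
title: "Learning patient similarity from heterogeneous EMR data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning patient similarity from heterogeneous EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patientsim)
```

## The problem

Electronic medical records mix data types that have no common notion of
distance: continuous demographics, binary flags, hierarchical ICD-10
diagnosis codes, sets of abnormal laboratory tests, and free-text report
phrases. `patientsim` implements a learning-based patient-similarity pipeline
for such data: feature-level similarities are computed per data type, a
Mahalanobis metric over the resulting pair-similarity vectors is learned from
a small expert-labeled set of patient pairs, the expert's scores are
propagated to all remaining pairs by a snowballing nearest-neighbour process,
and the learned similarity is evaluated in personalized kNN prediction of
four liver conditions (liver cancer, hemangioma, NAFLD, normal).

## Feature-level similarity

Each unordered patient pair is described by a 12-component vector, in the
fixed order returned by `similarity_components()`:

1. **Age** — `min(age_i, age_j) / max(age_i, age_j)`; equal ages (including
   0/0) score 1.
2. **Sex, drug-allergy history, admission source** — agreement indicators
   (1 if equal, 0 otherwise).
3. **Five independent report phrases** — agreement indicators on the binary
   presence of each clinically decisive phrase.
4. **Comorbidity conditions** — the information-content (IC) similarity
   described below.
5. **Laboratory tests** — Jaccard similarity of the two patients' sets of
   *abnormal* tests (labs are binarized 0 = normal / 1 = abnormal first).
6. **Text-feature sets** — Jaccard similarity of the remaining report-phrase
   sets.

### IC similarity over the ICD-10 hierarchy

ICD-10 codes are normalized to a leading letter plus at most three digits.
The *fragment corpus* counts, for every code occurrence in the cohort, all of
its prefixes (letter; letter + 1, 2, 3 digits). For two codes the nearest
common ancestor (NCA) is their longest common prefix, and

$$IC(c_1, c_2) = -\log p(\mathrm{NCA}),$$

with `p` the fragment's corpus frequency. Codes with different leading
letters share nothing and score 0. Because a prefix is counted at least as
often as any of its extensions, longer shared prefixes can only raise the IC,
and pairs sharing a *rare* family score higher than pairs sharing a common
one — the reason for preferring a corpus-based measure over edge counting.
The similarity of two comorbidity *sets* is the mean IC over all cross pairs
of codes.

Numerical choices, made here because no convention is universal:

* **Log base.** Natural log. Any base is a positive rescaling of IC and the
  min-max normalization below absorbs it.
* **Normalization.** The mean-IC value is unbounded above while the other 11
  components live in [0, 1], so before entering the pair vector it is
  min-max normalized over all cohort pairs — a monotone transform that
  preserves pair ordering. A pair of two empty comorbidity sets carries
  identical information and maps to 1; exactly one empty set maps to 0. If
  every pair has the same raw value the normalization is undefined; the
  component is set to 0.5 with a warning.
* **Empty sets in Jaccard similarities** follow the same convention:
  both empty = 1, one empty = 0.
* **Lab normal ranges** are treated as closed intervals: a value exactly on
  the boundary is normal. The convention is documented and tested; data
  providers using open intervals can pre-binarize instead.

### Laboratory preprocessing

Missing lab values are imputed with one CART tree per affected feature
(regression for continuous, classification for binary values), fitted on the
complete cases with all other labs plus the demographics as predictors —
minimum leaf size 5, standard variance-reduction/Gini splits, deterministic
given cohort order. A feature observed in no patient cannot be imputed and
raises an error. Binarization refuses missing values, so the pipeline order
(impute, then binarize) is enforced.

### Text features

Report phrases are ranked by a corpus-level TF-IDF score,
`score(t) = sum_d tf(t,d) * ln(N / df(t))` with raw term counts; the top
`r = 44` phrases (configurable) become the text features, ties broken
lexicographically. The aggregation across documents is a corpus-wide sum —
the simplest corpus-level statistic; the ranking, not the absolute score, is
what matters downstream. Five decisive phrases (radiologist-nominated in the
clinical setting; the generator's `independent_phrases()` in the synthetic
one) are independent binaries; the rest form the per-patient text set.
Phrases are treated as atomic tokens supplied upstream: segmentation of raw
clinical text is out of scope.

## Metric learning

Expert scores in [0, 1] for all pairs among a small patient sample are
discretized at the score tertiles into *cannot-link* / *general-link* /
*must-link* constraints. The tertile rule is rank-based with ties broken by
input position, so group sizes differ by at most one; whether the original
study cut on scores or ranks is unknowable from its description, and the
rank rule is the deterministic choice.

With `v_p` the pair vectors, within- and between-class scatter are exact sums
of `(v_p - v_q)(v_p - v_q)'` over all same- and different-constraint sample
pairs (computed through the Gram identity, which is algebraically exact). The
metric `C = A'A` minimizes the trace quotient

$$\lambda(A) = \frac{\mathrm{tr}(A S_w A')}{\mathrm{tr}(A S_b A')},
\qquad A A' = I_r,$$

via a decomposed Newton iteration: starting from `lambda_0 = 0` (so the first
iterate is the minimum-within-scatter subspace), each step takes the
eigenvectors of the `r` smallest eigenvalues of `S_w - lambda_t S_b` and
re-evaluates the quotient. The iterate sequence is non-increasing, bounded
below by 0, and stops at a 1e-8 change or 100 iterations (non-convergence
returns the best iterate with a warning). Eigenvector sign and tie handling
are fixed (ascending eigenvalue, first nonzero component positive) so the
result is deterministic. The solver is verified in the test suite against a
dense grid search over unit vectors on all d ≤ 3, r = 1 instances.

* **Projection rank `r`** defaults to 2 — the discriminant-analysis
  convention of one less than the number of constraint classes. `r = d` is
  disallowed: a square row-orthonormal `A` forces `C = I` and nothing is
  learned. Rank 1 is a reasonable alternative when the expert score is
  believed to be a single weighted sum; with rank 2 the second direction
  occasionally picks up a noise direction, which is why the recovery
  property is asserted over a family of seeds rather than each seed
  individually.

## Snowballing propagation

With `C` fixed, unlabeled pairs acquire scores in batches: each round, every
unlabeled pair's Mahalanobis distance to its nearest labeled pair is
computed, the `batch_size` closest pairs copy their nearest neighbour's score
and join the labeled set, and the process repeats until no pair is unscored.
Design choices the original description leaves open:

* **Batch membership** — smallest distance-to-nearest-labeled first (most
  confident first), the natural snowball.
* **Assignment** — scores are *copied* from the single nearest labeled
  neighbour, never averaged, so the final score multiset is a subset of the
  expert's values.
* **Batch size** — `max(1, round(0.0015 * n_unlabeled))`, the 0.15% rule; at
  the reference scale of 698,718 unlabeled pairs this gives 1048. The
  literal batch size 1153 quoted alongside that percentage can be passed
  explicitly via `batch_size`.
* **Determinism** — all ties break by canonical pair order (smaller id
  first, pairs sorted lexicographically), making the provenance log
  byte-identical across reruns.

The metric is never re-learned during propagation.

## Personalized kNN prediction

For the Euclidean arms the cohort is flattened to a numeric matrix: 44 text
binaries, 57 lab binaries, 26 popular-comorbidity binaries (codes occurring
in strictly more than 5% of patients) and 4 demographics — 131 features at
the reference group sizes. Age is min-max scaled to [0, 1] so the single
continuous column does not dominate Euclidean distances; no scaling rule
exists for this representation elsewhere, so the choice is documented here.
Codes defining the prediction outcome (C22, C78.7, D18.0, K76.0 for the
liver task) are excluded from comorbidity features before any similarity or
assembly via `exclude_outcome_codes()`.

Leave-one-out evaluation holds out each patient; the remaining patients form
the training pool, from which M% are selected randomly (`R`), by learned
similarity (`L`) or by Euclidean distance (`E`); the k = 10 nearest
neighbours under the learned similarity (`L`) or Euclidean distance (`E`)
vote with equal weight. Class probabilities are vote fractions; label ties
break by summed neighbour affinity, then canonical class order. A training
fraction that yields fewer than k samples is floored at k with a warning.
At M = 100% the selection mode is vacuous, so R+L and E+L coincide
prediction-for-prediction, as do R+E and L+E — an exact structural property
asserted in the tests.

Metrics: micro-averaged one-vs-rest ROC AUC (Mann–Whitney on the pooled
(score, indicator) pairs, ties counting 1/2), F1 (micro by default, equal to
accuracy for single-label multiclass prediction and consistent with the
explicitly micro AUC; macro available), and cross-entropy loss with natural
log and probabilities clipped at 1e-15 — vote fractions can be exactly zero
and the clip keeps the loss finite without materially changing non-degenerate
values.

## The synthetic cohort generator

Real EMR cohorts and expert similarity scores cannot be redistributed, so
the generator emulates the study conditions: four latent liver-condition
classes at proportions 153/178/403/449 out of 1183; class-conditional age
(means 66.6/57.2/51.4/51.8 years), male fraction, drug-allergy and
outpatient-admission rates taken from the reference population's descriptive
table; 1–11 comorbidity codes per patient drawn from a pool mixing common
comorbidities (hypertension, diabetes, lipid disorders, at the per-class
reference rates) with rare class-specific code families sharing a
three-character prefix; 57 binary labs at class-conditional abnormality
rates (0.08–0.12, the deliberately weak lab signal); and a 44-phrase report
vocabulary (5 independent + 39 set phrases) with class-conditional presence
probabilities. The hidden class labels are emitted in a separate field and
consumed only by the evaluation harness.

The expert is replaced by an oracle: `clip(w'v + eps, 0, 1)` with seeded
Gaussian noise. Default weights put 0.6 of their mass on the three
set-valued components (comorbidity, labs, text set) and spread the rest
uniformly — concentrated enough that metric-learning recovery is
identifiable, configurable for other experiments. Clipping happens after the
noise because expert scores are bounded by construction. The noise model
itself is an artifact choice; nothing is claimed about how a human expert's
errors are distributed.

What the generator does **not** emulate: realistic comorbidity co-occurrence
structure, longitudinal visits, unit heterogeneity in labs, or real
(Chinese-language) radiology text. Passing tests therefore demonstrate the
pipeline's correctness and its qualitative behaviour (learned similarity
recovering oracle structure, learned neighbours outperforming Euclidean ones
when class signal lives in hierarchical/set features), not clinical
performance on real data; headline real-data figures are not reproducible
without the original cohort.

## Problem sizes and reproducibility

The test suite and acceptance script run the full pipeline at desk scale:
cohorts of 30–200 patients (19,900 pairs at n = 200), 30 expert-labeled
patients (435 labeled pairs, matching the reference labeled-set size),
10-seed families for the stochastic recovery properties, and M grids of
{10, 25, 50, 100}%. These sizes were chosen to exercise every code path —
multi-round snowballing included — while keeping a full run in minutes on a
single CPU. All randomness flows through explicit seeds (configs, oracles
and selection all take one), and reruns are byte-identical.

## Known limitations

* The comorbidity component's min-max normalization depends on the cohort at
  hand; scores are comparable within a fitted model, not across cohorts.
* Propagated scores are 1-NN copies: they cannot express similarity values
  absent from the expert set, and early copying errors can snowball — the
  price of the method's simplicity.
* The trace-quotient objective is non-convex in `A`; the Newton scheme is
  the standard decomposed formulation and is grid-verified at low dimension,
  but global optimality in d = 12 is not guaranteed.
* `select_popular_comorbidities()` and the text schema are cohort-dependent;
  applying a fitted model to new patients requires refitting or freezing
  these artifacts explicitly.
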