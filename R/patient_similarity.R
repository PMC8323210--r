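#' Learn patient similarity from heterogeneous EMR data
#'
#' The package's central fitting function. Starting from a preprocessed
#' cohort (outcome codes excluded, labs imputed and binarized) and a small
#' expert-labeled set of patient pairs, it
#' \enumerate{
#'   \item computes the 12-component feature-similarity vector for every
#'     unordered patient pair (IC similarity over the ICD-10 fragment corpus,
#'     Jaccard similarities for the lab and text sets, agreement for binary
#'     features, min/max ratio for age);
#'   \item discretizes the expert scores into must-link / general-link /
#'     cannot-link constraints at the score tertiles, accumulates within- and
#'     between-class scatter over all labeled sample pairs, and learns a
#'     Mahalanobis metric `C = A'A` by trace-quotient minimization with a
#'     decomposed Newton iteration;
#'   \item propagates the expert scores to every remaining pair by
#'     snowballing batches of nearest labeled neighbours under the learned
#'     metric.
#' }
#' The result holds a similarity score for every patient pair and supports
#' `print`, `summary`, `coef` (the learned `C`), `plot` and `predict`
#' (personalized kNN disease-status prediction under leave-one-out
#' validation).
#'
#' @param cohort An `emr_cohort`, preprocessed: comorbidity codes normalized
#'   with outcome codes excluded, laboratory values imputed and binarized.
#' @param expert Data frame `id_a`, `id_b`, `score` of expert-scored pairs
#'   (scores in `[0, 1]`); typically all pairs among a small random patient
#'   subset. See [expert_label_pairs()] for the synthetic-oracle route.
#' @param rank Projection rank `r` of the learned metric (default 2, the
#'   number of constraint classes minus one).
#' @param batch_size Snowballing batch size; `NULL` for the 0.15% default.
#' @param schema A [text_schema()]; built from the cohort's reports
#'   ([build_text_schema()]) when `NULL`.
#' @param corpus A fragment corpus; built from the cohort when `NULL`.
#' @return Object of class `patient_similarity` with components `pairs`
#'   (scored pair table with provenance), `metric` (`metric_matrix`),
#'   `constraints`, `corpus`, `schema`, `cohort`, `expert_ids`, `call`.
#' @examples
#' cfg <- cohort_config(n_patients = 40, seed = 7)
#' cohort <- exclude_outcome_codes(generate_cohort(cfg))
#' schema <- build_text_schema(cohort, independent = independent_phrases())
#' pairs <- pairwise_similarity_table(cohort, schema = schema)
#' expert <- expert_label_pairs(pairs, cohort_ids(cohort)[1:10],
#'                              oracle_config(noise_sd = 0.02, seed = 7))
#' fit <- patient_similarity(cohort, expert, schema = schema)
#' fit
#' @export
patient_similarity <- function(cohort, expert, rank = 2L, batch_size = NULL,
                               schema = NULL, corpus = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!is.data.frame(expert) ||
      !all(c("id_a", "id_b", "score") %in% names(expert))) {
    stop("`expert` must be a data frame with id_a, id_b, score",
         call. = FALSE)
  }
  if (any(expert$score < 0 | expert$score > 1)) {
    stop("expert scores must lie in [0, 1]", call. = FALSE)
  }
  corpus <- corpus %||% build_fragment_corpus(cohort)
  schema <- schema %||% build_text_schema(cohort)
  pairs <- pairwise_similarity_table(cohort, corpus, schema)

  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  idx <- match(key(expert$id_a, expert$id_b), key(pairs$id_a, pairs$id_b))
  if (anyNA(idx)) {
    stop("expert pair(s) not found in cohort: ",
         paste(expert$id_a[is.na(idx)], expert$id_b[is.na(idx)],
               sep = "-", collapse = ", "), call. = FALSE)
  }
  pairs$score <- NA_real_
  pairs$score[idx] <- expert$score

  constraints <- assign_constraints(pairs$score[idx])
  V <- as.matrix(pairs[idx, similarity_components()])
  S <- scatter_matrices(V, constraints)
  metric <- solve_trace_quotient(S, r = rank)
  pairs <- propagate_scores(pairs, metric, batch_size = batch_size)

  structure(list(pairs = pairs, metric = metric, constraints = constraints,
                 scatter = S, corpus = corpus, schema = schema,
                 cohort = cohort,
                 expert_ids = sort(unique(c(expert$id_a, expert$id_b))),
                 call = match.call()),
            class = "patient_similarity")
}

#' @export
print.patient_similarity <- function(x, ...) {
  n <- length(x$cohort$patients)
  cat("Learned patient similarity\n")
  cat(sprintf("  cohort: %d patients, %d pairs (%d expert-labeled, %d propagated)\n",
              n, nrow(x$pairs), sum(x$pairs$round == 0),
              sum(x$pairs$round > 0)))
  cat(sprintf("  metric: d = %d, rank r = %d, trace quotient lambda* = %.4g\n",
              x$metric$d, x$metric$r, x$metric$lambda))
  cat(sprintf("  propagation: %d snowball rounds\n", max(x$pairs$round)))
  invisible(x)
}

#' @export
summary.patient_similarity <- function(object, ...) {
  w <- diag(object$metric$C)
  s <- object$pairs$score
  out <- list(
    n_patients = length(object$cohort$patients),
    n_pairs = nrow(object$pairs),
    n_labeled = sum(object$pairs$round == 0),
    rounds = max(object$pairs$round),
    lambda = object$metric$lambda,
    converged = object$metric$converged,
    iterations = object$metric$iterations,
    component_weights = stats::setNames(w / sum(w), similarity_components()),
    constraint_counts = table(object$constraints),
    score_summary = summary(s)
  )
  class(out) <- "summary.patient_similarity"
  out
}

#' @export
print.summary.patient_similarity <- function(x, ...) {
  cat("Learned patient similarity\n")
  cat(sprintf("  %d patients, %d pairs (%d labeled), %d snowball rounds\n",
              x$n_patients, x$n_pairs, x$n_labeled, x$rounds))
  cat(sprintf("  trace quotient lambda* = %.4g (%s, %d iterations)\n",
              x$lambda, if (x$converged) "converged" else "not converged",
              x$iterations))
  cat("  constraint classes:",
      paste(sprintf("%s=%d", names(x$constraint_counts), x$constraint_counts),
            collapse = ", "), "\n")
  cat("  metric diagonal mass by component:\n")
  print(round(x$component_weights, 3))
  cat("  propagated score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.patient_similarity <- function(object, ...) {
  object$metric$C
}

#' Similarity matrix of a fitted patient-similarity model
#'
#' @param object A [patient_similarity()] fit.
#' @return Symmetric patient-by-patient matrix of learned similarity scores.
#' @export
similarity_matrix <- function(object) {
  stopifnot(inherits(object, "patient_similarity"))
  score_matrix(object$pairs)
}

#' Display the learned metric
#'
#' Draws `|C|` as a shaded matrix over the 12 similarity components; dark
#' cells mark the component (pairs) the learned Mahalanobis metric weights
#' most.
#'
#' @param x A [patient_similarity()] fit.
#' @param ... Passed to [graphics::image()].
#' @export
plot.patient_similarity <- function(x, ...) {
  C <- abs(x$metric$C)
  comps <- similarity_components()
  d <- ncol(C)
  op <- graphics::par(mar = c(7, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(d), seq_len(d), t(C[d:1, , drop = FALSE]),
                  col = gray.colors(64, start = 1, end = 0),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Learned metric |C|", ...)
  graphics::axis(1, at = seq_len(d), labels = comps, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(d), labels = rev(comps), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Personalized kNN prediction from a fitted similarity model
#'
#' Runs the leave-one-out kNN disease-status evaluation using the fitted
#' model's propagated similarity scores (and, where the combination needs
#' it, the Euclidean numeric representation assembled from the stored
#' cohort).
#'
#' @param object A [patient_similarity()] fit whose cohort carries class
#'   labels.
#' @param combination Preset name `"R+L"`, `"R+E"`, `"L+E"` or `"E+L"`.
#' @param M_percent Training fraction in `(0, 100]`.
#' @param k Neighbours (default 10).
#' @param seed Seed for random training selection.
#' @param numeric_reps Optional precomputed [assemble_numeric()] matrix.
#' @param ... Unused.
#' @return A `prediction_run` (see [loo_evaluate()]).
#' @export
predict.patient_similarity <- function(object, combination = "R+L",
                                       M_percent = 100, k = 10L, seed = 1L,
                                       numeric_reps = NULL, ...) {
  spec <- combination_spec(combination, M_percent = M_percent, k = k,
                           seed = seed)
  needs_numeric <- spec$training_selection == "euclidean" ||
    spec$neighbor_metric == "euclidean"
  if (needs_numeric && is.null(numeric_reps)) {
    popular <- select_popular_comorbidities(object$cohort, 0.05)
    numeric_reps <- assemble_numeric(object$cohort, popular, object$schema)
  }
  loo_evaluate(object$cohort, spec, scores = similarity_matrix(object),
               numeric_reps = numeric_reps)
}
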