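#' kNN combination specification
#'
#' A personalized kNN run is specified by how the training samples are
#' selected from the training pool (random / by learned similarity / by
#' Euclidean distance), which metric identifies the k nearest neighbours
#' (learned similarity / Euclidean distance), the training fraction M% and k.
#' The four named presets follow the reference study:
#' `R+L` (random pool, learned neighbours), `R+E` (random, Euclidean),
#' `L+E` (learned pool, Euclidean neighbours), `E+L` (Euclidean pool,
#' learned neighbours).
#'
#' @param combination Preset name (`"R+L"`, `"R+E"`, `"L+E"`, `"E+L"`), or
#'   `NULL` to give `training_selection`/`neighbor_metric` explicitly.
#' @param M_percent Training fraction in `(0, 100]` (default 100).
#' @param k Number of neighbours (default 10).
#' @param seed Seed for random training selection.
#' @param training_selection One of `"random"`, `"learned"`, `"euclidean"`.
#' @param neighbor_metric One of `"learned"`, `"euclidean"`.
#' @return Object of class `combination_spec`.
#' @export
combination_spec <- function(combination = NULL, M_percent = 100, k = 10L,
                             seed = 1L, training_selection = "random",
                             neighbor_metric = "learned") {
  presets <- list(`R+L` = c("random", "learned"),
                  `R+E` = c("random", "euclidean"),
                  `L+E` = c("learned", "euclidean"),
                  `E+L` = c("euclidean", "learned"))
  if (!is.null(combination)) {
    if (!combination %in% names(presets)) {
      stop("unknown combination `", combination, "`; use ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    training_selection <- presets[[combination]][1]
    neighbor_metric <- presets[[combination]][2]
  }
  training_selection <- match.arg(training_selection,
                                  c("random", "learned", "euclidean"))
  neighbor_metric <- match.arg(neighbor_metric, c("learned", "euclidean"))
  if (!is.numeric(M_percent) || M_percent <= 0 || M_percent > 100) {
    stop("`M_percent` must lie in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(k) || k < 1) stop("`k` must be a positive integer",
                                    call. = FALSE)
  name <- names(presets)[vapply(presets, function(p) {
    p[1] == training_selection && p[2] == neighbor_metric
  }, logical(1))]
  structure(list(combination = if (length(name)) name else NA_character_,
                 training_selection = training_selection,
                 neighbor_metric = neighbor_metric,
                 M_percent = M_percent, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  cat(sprintf("kNN combination %s: training = %s (M = %g%%), neighbours = %s, k = %d\n",
              x$combination, x$training_selection, x$M_percent,
              x$neighbor_metric, x$k))
  invisible(x)
}

#' Similarity matrix from a propagated pair table
#'
#' @param pairs Data frame with `id_a`, `id_b`, `score` for every pair.
#' @return Symmetric matrix of scores with `NA` diagonal, rows/columns named
#'   by patient id.
#' @export
score_matrix <- function(pairs) {
  if (anyNA(pairs$score)) stop("pair table still has unscored pairs",
                               call. = FALSE)
  ids <- sort(unique(c(pairs$id_a, pairs$id_b)))
  S <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  ia <- match(pairs$id_a, ids)
  ib <- match(pairs$id_b, ids)
  S[cbind(ia, ib)] <- pairs$score
  S[cbind(ib, ia)] <- pairs$score
  S
}

#' Select training samples for one index patient
#'
#' Picks `round(M% * |pool|)` patients from the training pool — but never
#' fewer than `k` (a warning is issued when M% alone would give fewer) —
#' either uniformly at random (seeded), by highest learned similarity to the
#' index patient, or by smallest Euclidean distance on the numeric
#' representation. Ties are broken by canonical id order.
#'
#' @param pool_ids Candidate patient ids (excluding the index patient).
#' @param index_id The index (test) patient id.
#' @param spec A [combination_spec()].
#' @param scores Learned similarity matrix from [score_matrix()] (required
#'   for `learned` selection).
#' @param numeric_reps Numeric representation matrix from
#'   [assemble_numeric()] (required for `euclidean` selection).
#' @param seed Seed for random selection; defaults to `spec$seed`.
#' @return Character vector of selected training ids.
#' @export
select_training <- function(pool_ids, index_id, spec, scores = NULL,
                            numeric_reps = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "combination_spec"))
  if (index_id %in% pool_ids) {
    stop("the training pool must exclude the index patient", call. = FALSE)
  }
  npool <- length(pool_ids)
  m <- floor(spec$M_percent / 100 * npool + 0.5)
  if (m < spec$k) {
    warning("M = ", spec$M_percent, "% yields ", m, " < k = ", spec$k,
            " training samples; using k", call. = FALSE)
    m <- min(spec$k, npool)
  }
  pool_ids <- sort(pool_ids)
  switch(spec$training_selection,
    random = with_local_seed(seed, sort(sample(pool_ids, m))),
    learned = {
      if (is.null(scores)) stop("`scores` required for learned selection",
                                call. = FALSE)
      s <- scores[index_id, pool_ids]
      pool_ids[order(-s, pool_ids)][seq_len(m)]
    },
    euclidean = {
      if (is.null(numeric_reps)) {
        stop("`numeric_reps` required for euclidean selection", call. = FALSE)
      }
      delta <- numeric_reps[pool_ids, , drop = FALSE] -
        matrix(numeric_reps[index_id, ], npool, ncol(numeric_reps),
               byrow = TRUE)
      d <- sqrt(rowSums(delta^2))
      pool_ids[order(d, pool_ids)][seq_len(m)]
    })
}

#' kNN class probabilities for one index patient
#'
#' Identifies the k nearest training patients under the spec's neighbour
#' metric and returns vote-fraction class probabilities; the predicted label
#' is the majority class, with ties broken by the larger summed neighbour
#' similarity (or smaller summed distance) and then by canonical class order.
#'
#' @inheritParams select_training
#' @param training_ids Training patient ids (at least `k`).
#' @param labels Named character vector of true class labels.
#' @param classes Canonical class order (default: sorted unique labels).
#' @return List with `prob` (named probability vector summing to 1) and
#'   `label`.
#' @export
knn_predict <- function(index_id, training_ids, spec, labels, scores = NULL,
                        numeric_reps = NULL,
                        classes = sort(unique(labels))) {
  stopifnot(inherits(spec, "combination_spec"))
  k <- spec$k
  if (length(training_ids) < k) {
    stop("fewer training samples (", length(training_ids), ") than k = ", k,
         call. = FALSE)
  }
  training_ids <- sort(training_ids)
  if (spec$neighbor_metric == "learned") {
    if (is.null(scores)) stop("`scores` required for learned neighbours",
                              call. = FALSE)
    s <- scores[index_id, training_ids]
    if (anyNA(s)) stop("undefined learned similarity for some training pairs",
                       call. = FALSE)
    ord <- order(-s, training_ids)
    affinity <- s
  } else {
    if (is.null(numeric_reps)) {
      stop("`numeric_reps` required for euclidean neighbours", call. = FALSE)
    }
    delta <- numeric_reps[training_ids, , drop = FALSE] -
      matrix(numeric_reps[index_id, ], length(training_ids),
             ncol(numeric_reps), byrow = TRUE)
    d <- sqrt(rowSums(delta^2))
    ord <- order(d, training_ids)
    affinity <- -d  # larger is nearer for tie-breaking
  }
  nbrs <- training_ids[ord[seq_len(k)]]
  aff <- affinity[ord[seq_len(k)]]
  votes <- table(factor(labels[nbrs], levels = classes))
  prob <- as.numeric(votes) / k
  names(prob) <- classes
  top <- which(prob == max(prob))
  if (length(top) > 1L) {
    strength <- vapply(classes[top], function(cl) {
      sum(aff[labels[nbrs] == cl])
    }, numeric(1))
    top <- top[order(-strength, classes[top])][1]
  }
  list(prob = prob, label = classes[top[1]])
}

#' Leave-one-out evaluation of one kNN combination
#'
#' Each patient in turn is held out as the test sample; the remaining
#' patients form the training pool from which the spec's training samples
#' are drawn (random selection is re-seeded per round from `spec$seed`), and
#' the kNN vote yields a class-probability vector. Micro-averaged AUC,
#' F1-score and cross-entropy loss summarize the run.
#'
#' @param cohort An `emr_cohort` with `labels`.
#' @param spec A [combination_spec()].
#' @param scores Learned similarity matrix ([score_matrix()]); required when
#'   the spec uses the learned similarity.
#' @param numeric_reps Numeric representation ([assemble_numeric()]);
#'   required when the spec uses Euclidean distance.
#' @return Object of class `prediction_run`: list with `spec`, `prob`
#'   (patients x classes matrix), `predicted`, `truth`, `metrics` (named
#'   vector: `auc`, `f1`, `ce`).
#' @export
loo_evaluate <- function(cohort, spec, scores = NULL, numeric_reps = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(spec, "combination_spec"))
  labels <- cohort$labels
  if (is.null(labels)) stop("cohort has no class labels", call. = FALSE)
  ids <- cohort_ids(cohort)
  n <- length(ids)
  if (n < spec$k + 1L) stop("cohort smaller than k + 1", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  prob <- matrix(NA_real_, n, length(classes), dimnames = list(ids, classes))
  predicted <- character(n)
  for (i in seq_len(n)) {
    pool <- ids[-i]
    training <- select_training(pool, ids[i], spec, scores = scores,
                                numeric_reps = numeric_reps,
                                seed = spec$seed + i)
    res <- knn_predict(ids[i], training, spec, labels, scores = scores,
                       numeric_reps = numeric_reps, classes = classes)
    prob[i, ] <- res$prob
    predicted[i] <- res$label
  }
  metrics <- c(auc = micro_auc(prob, labels),
               f1 = f1_score(predicted, labels),
               ce = ce_loss(prob, labels))
  structure(list(spec = spec, prob = prob,
                 predicted = stats::setNames(predicted, ids),
                 truth = labels, classes = classes, metrics = metrics),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("kNN prediction run (%s, M = %g%%, k = %d): n = %d\n",
              x$spec$combination, x$spec$M_percent, x$spec$k, nrow(x$prob)))
  cat(sprintf("  micro-AUC %.3f, F1 %.3f, CE loss %.3f\n",
              x$metrics["auc"], x$metrics["f1"], x$metrics["ce"]))
  invisible(x)
}

#' Micro-averaged one-vs-rest ROC AUC
#'
#' For a matrix of class probabilities, every (patient, class) pair
#' contributes one pooled (score, is-true-class) observation; the AUC is the
#' Mann-Whitney statistic on the pooled set, with tied scores counting 1/2.
#' A numeric vector is treated as already-pooled binary scores with 0/1 (or
#' two-level) labels.
#'
#' @param prob Probability matrix (patients x classes, named columns) or a
#'   numeric score vector.
#' @param labels True class labels (character) or 0/1 indicators for the
#'   vector form.
#' @return AUC in `[0, 1]`.
#' @export
micro_auc <- function(prob, labels) {
  if (is.matrix(prob) || is.data.frame(prob)) {
    prob <- as.matrix(prob)
    if (length(unique(labels)) < 2L) {
      stop("micro-AUC needs at least 2 distinct classes", call. = FALSE)
    }
    pos <- as.vector(outer(as.character(labels), colnames(prob), "=="))
    scores <- as.vector(prob)
  } else {
    pos <- as.logical(as.numeric(labels))
    scores <- as.numeric(prob)
  }
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    stop("micro-AUC undefined: one of the pooled classes is empty",
         call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' F1-score for multiclass single-label predictions
#'
#' Micro averaging (the default) pools true/false positives over classes; for
#' single-label multiclass prediction the micro F1 equals overall accuracy.
#' Macro averaging (`average = "macro"`) averages per-class F1 over the
#' classes present in the truth, treating an undefined per-class F1 (no true
#' or predicted members) as 0.
#'
#' @param predicted,truth Aligned label vectors.
#' @param average `"micro"` or `"macro"`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(predicted, truth, average = c("micro", "macro")) {
  average <- match.arg(average)
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  }
  if (average == "micro") {
    return(mean(predicted == truth))
  }
  classes <- sort(unique(truth))
  f1s <- vapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Cross-entropy loss
#'
#' Mean negative natural-log probability assigned to the true class, with
#' probabilities clipped below at `eps` so vote fractions of exactly zero
#' stay finite.
#'
#' @param prob Probability matrix (patients x classes, named columns).
#' @param labels True class labels.
#' @param eps Clipping constant (default 1e-15).
#' @return Nonnegative loss.
#' @export
ce_loss <- function(prob, labels, eps = 1e-15) {
  prob <- as.matrix(prob)
  j <- match(as.character(labels), colnames(prob))
  if (anyNA(j)) stop("label absent from probability columns", call. = FALSE)
  p <- prob[cbind(seq_along(j), j)]
  -mean(log(pmax(p, eps)))
}

#' Run a grid of kNN combinations and training fractions
#'
#' One leave-one-out [loo_evaluate()] run per (combination, M, seed) cell.
#'
#' @param cohort An `emr_cohort` with labels.
#' @param combinations Character vector of preset names.
#' @param M_grid Numeric vector of training percentages.
#' @param k Neighbours (default 10).
#' @param seeds Integer vector of seeds for random training selection.
#' @param scores Learned similarity matrix.
#' @param numeric_reps Numeric representation matrix.
#' @return Data frame with columns `combination`, `M`, `seed`, `auc`, `f1`,
#'   `ce`; the full `prediction_run` objects are attached as attribute
#'   `runs` (named `combination/M/seed`).
#' @export
run_combination_grid <- function(cohort, combinations = c("R+L", "R+E",
                                                          "L+E", "E+L"),
                                 M_grid = c(10, 25, 50, 100), k = 10L,
                                 seeds = 1L, scores = NULL,
                                 numeric_reps = NULL) {
  rows <- list()
  runs <- list()
  for (combo in combinations) {
    for (M in M_grid) {
      for (seed in seeds) {
        spec <- combination_spec(combo, M_percent = M, k = k, seed = seed)
        run <- loo_evaluate(cohort, spec, scores = scores,
                            numeric_reps = numeric_reps)
        key <- sprintf("%s/M%g/s%d", combo, M, seed)
        runs[[key]] <- run
        rows[[key]] <- data.frame(combination = combo, M = M, seed = seed,
                                  auc = unname(run$metrics["auc"]),
                                  f1 = unname(run$metrics["f1"]),
                                  ce = unname(run$metrics["ce"]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}
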