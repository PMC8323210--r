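# small deterministic playground: labels and both metrics hand-constructed
toy_world <- function(n = 12, seed = 2) {
  set.seed(seed)
  ids <- sprintf("Q%02d", seq_len(n))
  labels <- setNames(rep(c("a", "b", "c"), length.out = n), ids)
  X <- matrix(rnorm(n * 4), n, dimnames = list(ids, paste0("f", 1:4)))
  # similarity: higher within class
  S <- matrix(runif(n * n, 0, 0.4), n, dimnames = list(ids, ids))
  S <- (S + t(S)) / 2
  same <- outer(labels, labels, "==")
  S[same] <- S[same] + 0.5
  diag(S) <- NA
  list(ids = ids, labels = labels, X = X, S = S)
}

test_that("combination presets map to the four selection/metric pairings", {
  expect_equal(combination_spec("R+L")$training_selection, "random")
  expect_equal(combination_spec("R+L")$neighbor_metric, "learned")
  expect_equal(combination_spec("R+E")$neighbor_metric, "euclidean")
  expect_equal(combination_spec("L+E")$training_selection, "learned")
  expect_equal(combination_spec("E+L")$training_selection, "euclidean")
  expect_error(combination_spec("X+Y"), "unknown")
  expect_error(combination_spec("R+L", M_percent = 0), "M_percent")
})

test_that("training selection honours mode, size and determinism", {
  w <- toy_world()
  pool <- setdiff(w$ids, "Q01")
  spec100 <- combination_spec("R+L", M_percent = 100, k = 3)
  expect_setequal(select_training(pool, "Q01", spec100, scores = w$S), pool)

  spec50 <- combination_spec(NULL, M_percent = 50, k = 3,
                             training_selection = "learned",
                             neighbor_metric = "euclidean")
  top <- select_training(pool, "Q01", spec50, scores = w$S)
  expect_length(top, round(0.5 * length(pool)))
  s <- sort(w$S["Q01", pool], decreasing = TRUE)
  expect_setequal(top, names(s)[seq_along(top)])

  specE <- combination_spec("E+L", M_percent = 30, k = 3)
  near <- select_training(pool, "Q01", specE, numeric_reps = w$X)
  d <- sqrt(colSums((t(w$X[pool, ]) - w$X["Q01", ])^2))
  expect_setequal(near, names(sort(d))[seq_along(near)])

  specR <- combination_spec("R+E", M_percent = 40, k = 3, seed = 9)
  expect_identical(select_training(pool, "Q01", specR, seed = 9),
                   select_training(pool, "Q01", specR, seed = 9))
  expect_error(select_training(w$ids, "Q01", spec100), "exclude")
  expect_warning(select_training(pool, "Q01",
                                 combination_spec("R+L", M_percent = 2, k = 3)),
                 "using k")
})

test_that("kNN voting yields vote-fraction probabilities and majority label", {
  w <- toy_world()
  # k = 3 with known neighbour labels: probabilities are vote fractions
  spec <- combination_spec("R+L", k = 3)
  res <- knn_predict("Q01", setdiff(w$ids, "Q01"), spec, w$labels,
                     scores = w$S)
  expect_equal(sum(res$prob), 1)
  expect_equal(res$label, names(which.max(res$prob)))
  nbrs <- names(sort(w$S["Q01", setdiff(w$ids, "Q01")],
                     decreasing = TRUE))[1:3]
  expect_equal(unname(res$prob[w$labels["Q01"]]),
               sum(w$labels[nbrs] == w$labels["Q01"]) / 3)

  # k = 1 with an exact duplicate: one-hot probability on its label
  X <- w$X
  X["Q02", ] <- X["Q01", ]
  spec1 <- combination_spec("R+E", k = 1)
  res1 <- knn_predict("Q01", setdiff(w$ids, "Q01"), spec1, w$labels,
                      numeric_reps = X)
  expect_equal(res1$label, unname(w$labels["Q02"]))
  expect_equal(unname(res1$prob[res1$label]), 1)

  expect_error(knn_predict("Q01", w$ids[2:3], spec, w$labels, scores = w$S),
               "fewer")
  # default k is 10
  expect_equal(combination_spec("R+L")$k, 10L)
})

test_that("micro-AUC matches the concordant-pair oracle and handles ties", {
  # binary scores: 3 of 4 positive-negative pairs concordant
  expect_equal(micro_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(micro_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)

  set.seed(13)
  for (i in 1:5) {
    n <- 30
    prob <- matrix(runif(n * 3), n)
    prob <- prob / rowSums(prob)
    colnames(prob) <- c("a", "b", "c")
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    pooled_scores <- as.vector(prob)
    pooled_pos <- as.vector(outer(labels, colnames(prob), "=="))
    expect_equal(micro_auc(prob, labels),
                 oracle_auc(pooled_scores, pooled_pos))
  }
  # perfect one-hot predictions give AUC 1
  onehot <- diag(3)[c(1, 2, 3), ]
  colnames(onehot) <- c("a", "b", "c")
  expect_equal(micro_auc(onehot, c("a", "b", "c")), 1)
  expect_error(micro_auc(onehot, c("a", "a", "a")), "2 distinct")
})

test_that("micro-AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(micro_auc(scores, labels), ref)
})

test_that("F1 and cross-entropy follow their definitions", {
  expect_equal(f1_score(c("a", "b", "c", "a"), c("a", "b", "c", "a")), 1)
  expect_equal(f1_score(c("a", "b", "c", "b"), c("a", "b", "c", "a")), 0.75)
  expect_equal(f1_score(c("b", "a"), c("a", "b")), 0)
  expect_error(f1_score("a", c("a", "b")), "length")
  # macro averaging over classes present in the truth
  expect_equal(f1_score(c("a", "a", "b"), c("a", "a", "a"), "macro"),
               2 * 2 / (2 * 2 + 0 + 1))
  expect_equal(f1_score(c("a", "b", "b"), c("a", "a", "b"), "macro"),
               mean(c(2 / 3, 2 / 3)))

  prob <- rbind(c(1, 0), c(0.5, 0.5))
  colnames(prob) <- c("a", "b")
  expect_equal(ce_loss(prob, c("a", "a")), -log(0.5) / 2)
  expect_equal(ce_loss(prob[1, , drop = FALSE], "a"), 0)
  # zero probability stays finite via clipping
  zero <- rbind(c(0, 1), c(1, 0))
  colnames(zero) <- c("a", "b")
  expect_equal(ce_loss(zero, c("a", "a")), -log(1e-15) / 2)
})

test_that("leave-one-out evaluation is complete, deterministic and sane", {
  w <- toy_world()
  cohort <- emr_cohort(lapply(w$ids, function(id) make_patient(id)),
                       labels = w$labels)
  spec <- combination_spec("R+E", M_percent = 100, k = 3, seed = 1)
  run <- loo_evaluate(cohort, spec, numeric_reps = w$X)
  expect_equal(nrow(run$prob), 12)
  expect_equal(rowSums(run$prob), setNames(rep(1, 12), w$ids))
  expect_true(all(run$metrics[c("auc", "f1")] >= 0 &
                    run$metrics[c("auc", "f1")] <= 1))
  expect_gte(run$metrics["ce"], 0)
  run2 <- loo_evaluate(cohort, spec, numeric_reps = w$X)
  expect_identical(run$prob, run2$prob)

  # perfectly separated clusters: flawless prediction
  ids <- sprintf("R%02d", 1:16)
  labels <- setNames(rep(c("w", "x", "y", "z"), each = 4), ids)
  centers <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  set.seed(5)
  X <- centers[rep(1:4, each = 4), ] + matrix(rnorm(32, 0, 0.1), 16)
  rownames(X) <- ids
  cl_cohort <- emr_cohort(lapply(ids, make_patient), labels = labels)
  run3 <- loo_evaluate(cl_cohort,
                       combination_spec("R+E", M_percent = 100, k = 3),
                       numeric_reps = X)
  expect_equal(unname(run3$metrics["auc"]), 1)
  expect_equal(unname(run3$metrics["f1"]), 1)
})

test_that("the combination grid reports one run per cell", {
  w <- toy_world()
  cohort <- emr_cohort(lapply(w$ids, function(id) make_patient(id)),
                       labels = w$labels)
  grid <- run_combination_grid(cohort, c("R+L", "R+E"), M_grid = c(50, 100),
                               k = 3, seeds = 1, scores = w$S,
                               numeric_reps = w$X)
  expect_equal(nrow(grid), 4)
  expect_named(grid, c("combination", "M", "seed", "auc", "f1", "ce"))
  expect_length(attr(grid, "runs"), 4)
})

test_that("at full training size the selection mode is vacuous", {
  w <- toy_world(n = 15, seed = 6)
  cohort <- emr_cohort(lapply(w$ids, function(id) make_patient(id)),
                       labels = w$labels)
  runs <- lapply(c("R+L", "E+L", "R+E", "L+E"), function(combo) {
    loo_evaluate(cohort, combination_spec(combo, M_percent = 100, k = 3),
                 scores = w$S, numeric_reps = w$X)
  })
  expect_identical(runs[[1]]$prob, runs[[2]]$prob)  # R+L == E+L
  expect_identical(runs[[3]]$prob, runs[[4]]$prob)  # R+E == L+E
  expect_identical(runs[[1]]$predicted, runs[[2]]$predicted)
  expect_identical(runs[[3]]$predicted, runs[[4]]$predicted)
})
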