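#' Constraint classes from expert similarity scores
#'
#' Expert similarity scores in `[0, 1]` are discretized into three constraint
#' classes at the upper and lower tertiles: the top third of pairs by score
#' become *must-link*, the bottom third *cannot-link*, and the middle third
#' *general-link*. The split is rank-based (ties broken by input position) so
#' the group sizes differ by at most one.
#'
#' @param scores Numeric vector of at least 3 similarity scores.
#' @return Factor with levels `cannot-link`, `general-link`, `must-link`, in
#'   input order.
#' @export
assign_constraints <- function(scores) {
  if (!is.numeric(scores) || length(scores) < 3L || anyNA(scores)) {
    stop("need at least 3 non-missing scores", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    warning("all similarity scores are equal; constraint classes are ",
            "assigned by input order only", call. = FALSE)
  }
  n <- length(scores)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(`cannot-link` = base + (rem >= 1L),
             `general-link` = base + (rem >= 2L),
             `must-link` = base)
  lv <- c("cannot-link", "general-link", "must-link")
  grp <- rep(lv, sizes)
  ord <- order(scores, seq_along(scores))  # ties by input index
  out <- character(n)
  out[ord] <- grp
  factor(out, levels = lv)
}

#' Within- and between-class scatter of labeled pair samples
#'
#' Over all unordered pairs `(p, q)` of labeled samples, accumulates the
#' outer products of the sample differences: `S_w` sums `(v_p - v_q)(v_p -
#' v_q)'` over same-constraint pairs and `S_b` over different-constraint
#' pairs, so `S_w + S_b` is the total scatter. The sums are computed exactly
#' through the Gram identity `sum_{p<q in G} dd' = |G| sum_G v v' - s s'`.
#'
#' @param V Numeric matrix (labeled samples x d) of pair-similarity vectors.
#' @param constraints Factor/vector of constraint classes, one per row of `V`
#'   (at least 2 distinct classes).
#' @return Object of class `scatter_matrices`: list with `S_w`, `S_b`,
#'   `n_within`, `n_between` (pair counts).
#' @export
scatter_matrices <- function(V, constraints) {
  V <- as.matrix(V)
  n <- nrow(V)
  if (length(constraints) != n) {
    stop("one constraint per sample required", call. = FALSE)
  }
  cls <- as.character(constraints)
  if (length(unique(cls)) < 2L) {
    stop("scatter requires at least 2 constraint classes", call. = FALSE)
  }
  scatter_of <- function(M) {
    m <- nrow(M)
    s <- colSums(M)
    m * crossprod(M) - tcrossprod(s)
  }
  S_tot <- scatter_of(V)
  S_w <- matrix(0, ncol(V), ncol(V))
  n_within <- 0L
  for (g in unique(cls)) {
    Vg <- V[cls == g, , drop = FALSE]
    if (nrow(Vg) >= 2L) {
      S_w <- S_w + scatter_of(Vg)
      n_within <- n_within + choose(nrow(Vg), 2L)
    }
  }
  S_b <- S_tot - S_w
  # enforce exact symmetry against floating-point drift
  S_w <- (S_w + t(S_w)) / 2
  S_b <- (S_b + t(S_b)) / 2
  structure(list(S_w = S_w, S_b = S_b,
                 n_within = as.integer(n_within),
                 n_between = as.integer(choose(n, 2L) - n_within)),
            class = "scatter_matrices")
}

#' Trace-quotient metric learning by decomposed Newton iteration
#'
#' Finds a row-orthonormal projection `A` (r x d) minimizing the trace
#' quotient `tr(A S_w A') / tr(A S_b A')` — within-class over between-class
#' scatter — and returns the positive semi-definite Mahalanobis matrix
#' `C = A'A`. The Newton iteration on the quotient value `lambda` starts at
#' `lambda_0 = 0`; at each step `A_t` collects the eigenvectors of the `r`
#' smallest eigenvalues of `S_w - lambda_t S_b` and `lambda_{t+1} =
#' tr(A_t S_w A_t') / tr(A_t S_b A_t')`. The `lambda` sequence is
#' non-increasing and the iteration stops when it changes by less than `tol`.
#'
#' @param S A [scatter_matrices()] object (or list with `S_w`, `S_b`).
#' @param r Projection rank, `1 <= r < d` (default 2, the number of
#'   constraint classes minus one).
#' @param tol Convergence tolerance on `lambda` (default 1e-8).
#' @param max_iter Iteration cap (default 100); non-convergence yields a
#'   warning and the best iterate.
#' @return Object of class `metric_matrix`: list with `C` (d x d PSD matrix),
#'   `A` (r x d, orthonormal rows), `lambda` (achieved quotient), `lambdas`
#'   (iterate sequence), `iterations`, `converged`, `r`, `d`.
#' @export
solve_trace_quotient <- function(S, r = 2L, tol = 1e-8, max_iter = 100L) {
  S_w <- as.matrix(S$S_w)
  S_b <- as.matrix(S$S_b)
  d <- nrow(S_w)
  stopifnot(nrow(S_b) == d, ncol(S_w) == d, ncol(S_b) == d)
  if (r < 1L || r >= d) {
    stop("projection rank must satisfy 1 <= r < d (r = d would force ",
         "C = identity)", call. = FALSE)
  }
  if (max(abs(S_b)) < 1e-12) {
    stop("between-class scatter is (numerically) zero; the trace quotient ",
         "is undefined", call. = FALSE)
  }
  lambda <- 0
  lambdas <- numeric(0)
  A <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M <- S_w - lambda * S_b
    eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
    # r smallest eigenvalues, ascending; deterministic sign convention
    idx <- d - seq_len(r) + 1L
    A_new <- t(eig$vectors[, rev(idx), drop = FALSE])
    A_new <- fix_signs(A_new)
    num <- sum((A_new %*% S_w) * A_new)
    den <- sum((A_new %*% S_b) * A_new)
    if (den <= 1e-15) {
      # projection annihilates S_b: quotient degenerates; keep previous iterate
      if (is.null(A)) {
        stop("between-class scatter vanishes on the minimum-within subspace",
             call. = FALSE)
      }
      break
    }
    A <- A_new
    lambda_new <- num / den
    lambdas <- c(lambdas, lambda_new)
    if (abs(lambda_new - lambda) < tol) {
      lambda <- lambda_new
      converged <- TRUE
      break
    }
    lambda <- lambda_new
  }
  if (!converged) {
    warning("trace-quotient Newton iteration did not converge in ", max_iter,
            " steps; returning best iterate", call. = FALSE)
  }
  structure(list(C = crossprod(A), A = A, lambda = lambda, lambdas = lambdas,
                 iterations = length(lambdas), converged = converged,
                 r = as.integer(r), d = as.integer(d)),
            class = "metric_matrix")
}

# make the first nonzero entry of each row positive (deterministic eigvecs)
fix_signs <- function(A) {
  for (i in seq_len(nrow(A))) {
    j <- which(abs(A[i, ]) > 1e-12)[1]
    if (!is.na(j) && A[i, j] < 0) A[i, ] <- -A[i, ]
  }
  A
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat("Learned Mahalanobis metric (trace-quotient minimization)\n")
  cat(sprintf("  d = %d, projection rank r = %d\n", x$d, x$r))
  cat(sprintf("  achieved quotient lambda* = %.6g (%s in %d iteration%s)\n",
              x$lambda, if (x$converged) "converged" else "NOT converged",
              x$iterations, if (x$iterations == 1) "" else "s"))
  invisible(x)
}

#' Mahalanobis distance between pair-similarity vectors
#'
#' `d_m(v_p, v_q) = sqrt((v_p - v_q)' C (v_p - v_q))` for a positive
#' semi-definite matrix `C`. With `C` the identity this is the Euclidean
#' distance.
#'
#' @param v_p,v_q Numeric vectors of equal length.
#' @param C A `metric_matrix` object or a PSD matrix.
#' @return Nonnegative distance.
#' @export
mahalanobis_distance <- function(v_p, v_q, C) {
  if (inherits(C, "metric_matrix")) C <- C$C
  C <- as.matrix(C)
  if (length(v_p) != length(v_q) || length(v_p) != nrow(C) ||
      nrow(C) != ncol(C)) {
    stop("dimension mismatch between vectors and metric", call. = FALSE)
  }
  delta <- as.numeric(v_p) - as.numeric(v_q)
  sqrt(max(0, drop(t(delta) %*% C %*% delta)))
}

#' Identity metric
#'
#' Convenience constructor for the unlearned baseline metric `C = I_d`,
#' usable wherever a `metric_matrix` is accepted.
#'
#' @param d Dimension (default 12).
#' @return A `metric_matrix` with `C = diag(d)`.
#' @export
identity_metric <- function(d = 12L) {
  structure(list(C = diag(d), A = diag(d), lambda = NA_real_,
                 lambdas = numeric(0), iterations = 0L, converged = TRUE,
                 r = as.integer(d), d = as.integer(d)),
            class = "metric_matrix")
}

# factor R (k x d) with C = R'R, for fast projected distances
metric_root <- function(C) {
  if (inherits(C, "metric_matrix")) {
    if (!is.null(C$A)) return(C$A)
    C <- C$C
  }
  C <- as.matrix(C)
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop("metric matrix is not positive semi-definite", call. = FALSE)
  }
  keep <- eig$values > 1e-12
  if (!any(keep)) return(matrix(0, 1L, nrow(C)))
  t(eig$vectors[, keep, drop = FALSE]) * sqrt(eig$values[keep])
}
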