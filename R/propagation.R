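#' Default snowballing batch size
#'
#' The batch size for one snowballing round defaults to 0.15% of the
#' unlabeled samples, floored at one: `max(1, round(0.0015 * n_unlabeled))`.
#' Any positive integer may be passed explicitly instead (e.g. the reference
#' study's 1153).
#'
#' @param n_unlabeled Number of unlabeled pair samples (>= 1).
#' @return Positive integer batch size.
#' @export
default_batch_size <- function(n_unlabeled) {
  if (!is.numeric(n_unlabeled) || n_unlabeled < 1) {
    stop("`n_unlabeled` must be >= 1", call. = FALSE)
  }
  max(1L, as.integer(round(0.0015 * n_unlabeled)))
}

#' Snowballing propagation of similarity scores
#'
#' Semi-supervised expansion of the expert-labeled pair set. Each round, the
#' Mahalanobis distance (under the fixed learned metric) from every unlabeled
#' pair sample to its nearest labeled sample is computed; the `batch_size`
#' unlabeled samples with the smallest such distance copy their nearest
#' labeled neighbour's score and join the labeled set, which then serves as
#' the neighbour pool for the next round. The process repeats until every
#' pair carries a score. Scores are copied, never interpolated, so the final
#' score values are a subset of the initial expert scores. Ties are broken by
#' canonical pair order, making the procedure fully deterministic.
#'
#' @param pairs Data frame as returned by [pairwise_similarity_table()] with
#'   an additional `score` column: expert scores in `[0, 1]` for labeled
#'   pairs, `NA` for unlabeled pairs.
#' @param metric A `metric_matrix` (see [solve_trace_quotient()]) or PSD
#'   matrix; fixed throughout.
#' @param batch_size Positive integer; defaults to
#'   [default_batch_size()] of the number of unlabeled pairs.
#' @return `pairs` with `score` filled for every row plus provenance columns
#'   `source_id_a`, `source_id_b` (the labeled pair each score was copied
#'   from; `NA` for seed pairs) and `round` (0 for seed pairs).
#' @export
propagate_scores <- function(pairs, metric, batch_size = NULL) {
  comps <- similarity_components()
  if (!all(comps %in% names(pairs))) {
    stop("`pairs` must contain the 12 similarity components", call. = FALSE)
  }
  if (!"score" %in% names(pairs)) stop("`pairs` needs a `score` column",
                                       call. = FALSE)
  labeled <- which(!is.na(pairs$score))
  if (length(labeled) == 0L) stop("no labeled pairs to propagate from",
                                  call. = FALSE)
  sc <- pairs$score[labeled]
  if (any(sc < 0 | sc > 1)) stop("scores must lie in [0, 1]", call. = FALSE)

  n <- nrow(pairs)
  pairs$source_id_a <- NA_character_
  pairs$source_id_b <- NA_character_
  pairs$round <- NA_integer_
  pairs$round[labeled] <- 0L
  unlabeled <- setdiff(seq_len(n), labeled)
  if (length(unlabeled) == 0L) return(pairs)

  R <- metric_root(metric)
  Z <- as.matrix(pairs[comps]) %*% t(R)
  batch <- batch_size %||% default_batch_size(length(unlabeled))
  if (batch < 1L) stop("`batch_size` must be >= 1", call. = FALSE)

  # nearest labeled neighbour, maintained incrementally:
  # best_dist/best_src track each unlabeled sample's current nearest
  nn <- nearest_rows(Z, unlabeled, labeled)
  best_dist <- nn$dist
  best_src <- nn$src
  round_no <- 0L
  while (length(unlabeled)) {
    round_no <- round_no + 1L
    take <- min(batch, length(unlabeled))
    sel <- order(best_dist, unlabeled)[seq_len(take)]  # ties: canonical order
    new_idx <- unlabeled[sel]
    src_idx <- best_src[sel]
    pairs$score[new_idx] <- pairs$score[src_idx]
    pairs$source_id_a[new_idx] <- pairs$id_a[src_idx]
    pairs$source_id_b[new_idx] <- pairs$id_b[src_idx]
    pairs$round[new_idx] <- round_no
    unlabeled <- unlabeled[-sel]
    best_dist <- best_dist[-sel]
    best_src <- best_src[-sel]
    if (length(unlabeled)) {
      upd <- nearest_rows(Z, unlabeled, sort(new_idx))
      better <- upd$dist < best_dist
      best_dist[better] <- upd$dist[better]
      best_src[better] <- upd$src[better]
    }
  }
  pairs
}

# for each row index in `from`, the nearest row among `to` (projected coords);
# ties resolved toward the smaller target index
nearest_rows <- function(Z, from, to, chunk = 2048L) {
  nf <- length(from)
  dist <- numeric(nf)
  src <- integer(nf)
  sq_to <- rowSums(Z[to, , drop = FALSE]^2)
  Zt <- Z[to, , drop = FALSE]
  for (start in seq(1L, nf, by = chunk)) {
    sel <- start:min(start + chunk - 1L, nf)
    Zf <- Z[from[sel], , drop = FALSE]
    D2 <- outer(rowSums(Zf^2), sq_to, "+") - 2 * tcrossprod(Zf, Zt)
    D2[D2 < 0] <- 0
    j <- max.col(-D2, ties.method = "first")
    dist[sel] <- sqrt(D2[cbind(seq_along(sel), j)])
    src[sel] <- to[j]
  }
  list(dist = dist, src = src)
}
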