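#' Text feature schema
#'
#' Radiology reports are reduced to binary phrase indicators. A small set of
#' clinically decisive phrases (by default five, e.g. "arterial phase") is
#' treated as independent binary features; the remaining representative
#' phrases form a single binary feature *set* per patient, compared between
#' patients with Jaccard similarity.
#'
#' @param independent Ordered character vector of independent phrases.
#' @param set Character vector of set-feature phrases (disjoint from
#'   `independent`).
#' @return An object of class `text_schema`.
#' @export
text_schema <- function(independent, set) {
  independent <- as.character(independent)
  set <- as.character(set)
  if (length(independent) == 0L && length(set) == 0L) {
    stop("empty text schema", call. = FALSE)
  }
  if (length(intersect(independent, set))) {
    stop("phrase(s) in both schema lists: ",
         paste(intersect(independent, set), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(c(independent, set))) stop("duplicate phrases in schema",
                                               call. = FALSE)
  structure(list(independent = independent, set = set), class = "text_schema")
}

#' @export
print.text_schema <- function(x, ...) {
  cat("Text schema:", length(x$independent), "independent phrases,",
      length(x$set), "set phrases\n")
  invisible(x)
}

#' Corpus-level TF-IDF ranking of report phrases
#'
#' Scores every distinct phrase across all patients' report-token multisets
#' with `score(t) = sum_d tf(t, d) * ln(N / df(t))`, where `tf` is the raw
#' count of `t` in document `d`, `N` the number of documents and `df(t)` the
#' number of documents containing `t`. Phrases are ranked by descending score
#' with ties broken lexicographically.
#'
#' @param reports List (one element per patient) of character vectors of
#'   tokens; repetitions count toward term frequency.
#' @return Data frame with columns `phrase`, `score`, ordered by rank.
#' @export
tfidf_rank <- function(reports) {
  if (!is.list(reports) || length(reports) < 2L) {
    stop("TF-IDF needs at least 2 documents", call. = FALSE)
  }
  n_docs <- length(reports)
  tf <- table(unlist(reports, use.names = FALSE))
  df <- table(unlist(lapply(reports, unique), use.names = FALSE))
  phrases <- names(tf)
  if (any(!nzchar(phrases))) stop("empty token encountered", call. = FALSE)
  score <- as.numeric(tf) * log(n_docs / as.numeric(df[phrases]))
  out <- data.frame(phrase = phrases, score = score)
  out[order(-out$score, out$phrase), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Top-r phrases of a TF-IDF ranking
#'
#' @param ranked Output of [tfidf_rank()].
#' @param r Number of phrases to keep (`0 <= r <=` vocabulary size).
#' @return Character vector of `r` phrases.
#' @export
select_top_r <- function(ranked, r) {
  if (!is.numeric(r) || r < 0 || r != round(r)) {
    stop("`r` must be a nonnegative integer", call. = FALSE)
  }
  if (r > nrow(ranked)) {
    stop("r = ", r, " exceeds vocabulary size ", nrow(ranked), call. = FALSE)
  }
  ranked$phrase[seq_len(r)]
}

#' Build a text schema from a cohort's reports
#'
#' Ranks all report phrases by corpus-level TF-IDF, keeps the top `r`, and
#' splits them into independent features and set features. When the decisive
#' phrases are known (e.g. supplied by a radiologist) pass them as
#' `independent`; otherwise the `n_independent` top-ranked phrases are used.
#'
#' @param cohort An `emr_cohort`.
#' @param r Total number of text features (default 44).
#' @param independent Optional character vector of independent phrases (must
#'   be among the selected `r`).
#' @param n_independent Number of independent features when `independent` is
#'   `NULL` (default 5).
#' @return A [text_schema()].
#' @export
build_text_schema <- function(cohort, r = 44, independent = NULL,
                              n_independent = 5) {
  stopifnot(inherits(cohort, "emr_cohort"))
  ranked <- tfidf_rank(lapply(cohort$patients, `[[`, "report_tokens"))
  top <- select_top_r(ranked, min(r, nrow(ranked)))
  if (is.null(independent)) {
    independent <- top[seq_len(min(n_independent, length(top)))]
  } else if (!all(independent %in% top)) {
    top <- c(independent, setdiff(top, independent))[seq_len(length(top))]
  }
  text_schema(independent, setdiff(top, independent))
}

#' Structure reports into binary features
#'
#' Applies a [text_schema()] to every patient: each independent phrase becomes
#' a named 0/1 column (1 when the phrase occurs among the patient's report
#' tokens), and the set phrases present in the report form the patient's
#' text-feature set. Token order and multiplicity are irrelevant (presence
#' semantics).
#'
#' @param cohort An `emr_cohort`.
#' @param schema A [text_schema()].
#' @return List with `independent` (patients x phrases 0/1 matrix) and `sets`
#'   (named list of character vectors, each a subset of `schema$set`).
#' @export
structure_reports <- function(cohort, schema) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(schema, "text_schema"))
  ids <- cohort_ids(cohort)
  ind <- presence_matrix(lapply(cohort$patients, `[[`, "report_tokens"),
                         schema$independent)
  rownames(ind) <- ids
  sets <- lapply(cohort$patients, function(p) {
    schema$set[schema$set %in% p$report_tokens]
  })
  names(sets) <- ids
  list(independent = ind, sets = sets)
}
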