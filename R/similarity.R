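#' ICD-10 fragment corpus
#'
#' The corpus underlying the information-content (IC) similarity. For every
#' ICD-10 code occurrence in every patient's comorbidity list, all prefixes of
#' the code (the leading letter alone, and the letter plus one, two or three
#' digits) are counted once. The probability of a fragment is its count over
#' the corpus total, so common disease families receive low IC and rare ones
#' high IC — two patients sharing a rare disease are more alike than two
#' sharing a common one.
#'
#' @param cohort An `emr_cohort` with normalized comorbidity codes.
#' @return An object of class `fragment_corpus`: list with `counts` (named
#'   integer vector) and `total`.
#' @export
build_fragment_corpus <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  codes <- unlist(lapply(cohort$patients, `[[`, "comorbidities"),
                  use.names = FALSE)
  if (length(codes) == 0L) {
    stop("cohort has no comorbidity codes; cannot build fragment corpus",
         call. = FALSE)
  }
  codes <- normalize_icd(codes)
  frags <- unlist(lapply(codes, function(x) {
    substring(x, 1L, seq_len(nchar(x)))
  }), use.names = FALSE)
  counts <- table(frags)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 total = length(frags)),
            class = "fragment_corpus")
}

#' @export
print.fragment_corpus <- function(x, ...) {
  cat("ICD-10 fragment corpus:", length(x$counts), "distinct fragments,",
      "total count", x$total, "\n")
  invisible(x)
}

longest_common_prefix <- function(a, b) {
  k <- 0L
  m <- min(nchar(a), nchar(b))
  while (k < m && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  substr(a, 1L, k)
}

#' Information content of a pair of ICD-10 codes
#'
#' `IC(code1, code2) = -log(p(NCA))` where the NCA (nearest common ancestor)
#' is the longest common prefix of the two normalized codes and `p` is its
#' frequency in the fragment corpus. Codes with different leading letters
#' share no information and score 0. The natural logarithm is used.
#'
#' @param code1,code2 Normalized ICD-10 codes.
#' @param corpus A [build_fragment_corpus()] result covering both codes.
#' @return Nonnegative IC value.
#' @export
ic_pair <- function(code1, code2, corpus) {
  stopifnot(inherits(corpus, "fragment_corpus"))
  code1 <- normalize_icd(code1)
  code2 <- normalize_icd(code2)
  nca <- longest_common_prefix(code1, code2)
  if (!nzchar(nca)) return(0)
  cnt <- corpus$counts[nca]
  if (is.na(cnt)) {
    stop("fragment `", nca, "` absent from corpus (corpus/cohort mismatch)",
         call. = FALSE)
  }
  -log(as.numeric(cnt) / corpus$total)
}

#' Comorbidity-condition similarity of two code sets
#'
#' The average IC over all cross pairs of the two patients' comorbidity sets:
#' `(1/(m n)) * sum_a sum_b IC(ICD_a, ICD_b)`. The raw value is unbounded
#' above; within [pairwise_similarity_table()] it is min-max normalized over
#' the cohort's pairs before entering the 12-component similarity vector.
#' When exactly one set is empty the similarity is 0; when both are empty the
#' raw value is `NA` (mapped to 1, identical information, by the normalizing
#' table).
#'
#' @param x,y Character vectors of normalized ICD-10 codes (outcome codes
#'   already excluded).
#' @inheritParams ic_pair
#' @return Nonnegative mean IC (or `NA` for two empty sets).
#' @export
comorbidity_similarity <- function(x, y, corpus) {
  if (length(x) == 0L && length(y) == 0L) return(NA_real_)
  if (length(x) == 0L || length(y) == 0L) return(0)
  tot <- 0
  for (a in x) for (b in y) tot <- tot + ic_pair(a, b, corpus)
  tot / (length(x) * length(y))
}

#' Elementary feature similarities
#'
#' `binary_similarity()` is 1 when two 0/1 features agree and 0 otherwise.
#' `jaccard_set_similarity()` is `|A n B| / |A u B|`, with two empty sets
#' scoring 1 (identical information) and exactly one empty set scoring 0.
#' `age_similarity()` is `min(age1, age2) / max(age1, age2)`, with two equal
#' ages (including 0/0) scoring 1.
#'
#' @param a,b Binary scalars in \{0, 1\}.
#' @return Similarity in `[0, 1]`.
#' @export
binary_similarity <- function(a, b) {
  if (!is_binary01(c(a, b)) || anyNA(c(a, b))) {
    stop("binary_similarity() needs 0/1 inputs", call. = FALSE)
  }
  as.numeric(a == b)
}

#' @rdname binary_similarity
#' @param A,B Sets (vectors of unique-able elements).
#' @export
jaccard_set_similarity <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  if (length(A) == 0L && length(B) == 0L) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

#' @rdname binary_similarity
#' @param age1,age2 Nonnegative ages in years.
#' @export
age_similarity <- function(age1, age2) {
  if (age1 < 0 || age2 < 0) stop("ages must be nonnegative", call. = FALSE)
  if (age1 == age2) return(1)
  min(age1, age2) / max(age1, age2)
}

#' Names of the 12 pair-similarity components
#'
#' Fixed component order of the pair-similarity vector: age, sex,
#' drug-allergy, admission-source, the five independent text features, the
#' (normalized) comorbidity IC similarity, the Jaccard similarity of abnormal
#' laboratory-test sets, and the Jaccard similarity of report text-feature
#' sets.
#'
#' @return Character vector of length 12.
#' @export
similarity_components <- function() {
  c("age", "sex", "drug_allergy", "admission_source",
    paste0("text_", 1:5), "comorbidity", "labs", "text_set")
}

#' Pair similarity vector for two patients
#'
#' Computes the 12-component feature-level similarity vector for one patient
#' pair. The comorbidity component is returned raw (mean IC) unless
#' `comorbidity_range` is supplied, in which case it is min-max normalized
#' with the given `(min, max)` (two empty sets map to 1, one empty to 0).
#'
#' @param p_i,p_j Patient records from an `emr_cohort` with binarized labs.
#' @param corpus A [build_fragment_corpus()] result.
#' @param schema A [text_schema()] with 5 independent phrases.
#' @param comorbidity_range Optional numeric `c(min, max)` of raw comorbidity
#'   similarities over the cohort's pairs.
#' @return Named numeric vector of length 12 (see [similarity_components()]).
#' @export
pair_similarity_vector <- function(p_i, p_j, corpus, schema,
                                   comorbidity_range = NULL) {
  stopifnot(inherits(schema, "text_schema"))
  if (length(schema$independent) != 5L) {
    stop("the pair-similarity vector requires exactly 5 independent text ",
         "features (got ", length(schema$independent), ")", call. = FALSE)
  }
  if (anyNA(p_i$labs) || anyNA(p_j$labs) ||
      !is_binary01(p_i$labs) || !is_binary01(p_j$labs)) {
    stop("labs must be imputed and binarized before similarity computation",
         call. = FALSE)
  }
  ind <- vapply(schema$independent, function(ph) {
    binary_similarity(as.numeric(ph %in% p_i$report_tokens),
                      as.numeric(ph %in% p_j$report_tokens))
  }, numeric(1))
  cm <- comorbidity_similarity(p_i$comorbidities, p_j$comorbidities, corpus)
  if (!is.null(comorbidity_range)) {
    cm <- normalize_comorbidity(cm, comorbidity_range)
  }
  labs_i <- names(p_i$labs)[p_i$labs == 1]
  labs_j <- names(p_j$labs)[p_j$labs == 1]
  set_i <- schema$set[schema$set %in% p_i$report_tokens]
  set_j <- schema$set[schema$set %in% p_j$report_tokens]
  v <- c(age_similarity(p_i$age, p_j$age),
         binary_similarity(p_i$sex, p_j$sex),
         binary_similarity(p_i$drug_allergy, p_j$drug_allergy),
         binary_similarity(p_i$admission_source, p_j$admission_source),
         ind,
         cm,
         jaccard_set_similarity(labs_i, labs_j),
         jaccard_set_similarity(set_i, set_j))
  stats::setNames(v, similarity_components())
}

# min-max normalization of raw comorbidity similarities; NA (both sets empty)
# maps to 1, degenerate constant range to 0.5
normalize_comorbidity <- function(x, range) {
  lo <- range[1]
  hi <- range[2]
  out <- if (hi > lo) pmin(1, pmax(0, (x - lo) / (hi - lo))) else {
    rep(0.5, length(x))
  }
  out[is.na(x)] <- 1
  out
}

#' All pairwise similarity vectors of a cohort
#'
#' Enumerates all `n (n - 1) / 2` unordered patient pairs in canonical order
#' (lexicographically smaller id first, pairs sorted by first then second id)
#' and computes the 12 similarity components for each. The comorbidity
#' component is min-max normalized to `[0, 1]` over all pairs (a monotone
#' rescaling; both-empty pairs map to 1, one-empty pairs to 0). If every pair
#' has the same raw comorbidity similarity the component is set to 0.5 with a
#' warning.
#'
#' @param cohort An `emr_cohort` (>= 2 patients, labs binarized).
#' @param corpus Optional [build_fragment_corpus()]; built from the cohort
#'   when `NULL`.
#' @param schema A [text_schema()].
#' @return Data frame with columns `id_a`, `id_b` and the 12 components of
#'   [similarity_components()], plus attribute `comorbidity_range`.
#' @export
pairwise_similarity_table <- function(cohort, corpus = NULL, schema) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(schema, "text_schema"))
  if (length(schema$independent) != 5L) {
    stop("the pair-similarity vector requires exactly 5 independent text ",
         "features (got ", length(schema$independent), ")", call. = FALSE)
  }
  ids <- cohort_ids(cohort)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 patients", call. = FALSE)
  ord <- order(ids)
  patients <- cohort$patients[ord]
  ids <- ids[ord]
  corpus <- corpus %||% build_fragment_corpus(cohort)

  age <- vapply(patients, `[[`, numeric(1), "age")
  AgeS <- outer(age, age, pmin) / outer(age, age, pmax)
  AgeS[outer(age, age, pmax) == 0] <- 1

  demo_sim <- function(field) {
    x <- vapply(patients, `[[`, numeric(1), field)
    if (!is_binary01(x)) stop("`", field, "` must be 0/1", call. = FALSE)
    outer(x, x, "==") * 1
  }
  SexS <- demo_sim("sex")
  AllS <- demo_sim("drug_allergy")
  AdmS <- demo_sim("admission_source")

  tokens <- lapply(patients, `[[`, "report_tokens")
  IndM <- presence_matrix(tokens, schema$independent)
  IndS <- lapply(seq_along(schema$independent), function(j) {
    outer(IndM[, j], IndM[, j], "==") * 1
  })

  labsM <- do.call(rbind, lapply(patients, function(p) {
    if (anyNA(p$labs) || !is_binary01(p$labs)) {
      stop("labs must be imputed and binarized before similarity computation",
           call. = FALSE)
    }
    p$labs
  }))
  LabS <- jaccard_matrix(labsM)
  SetM <- presence_matrix(tokens, schema$set)
  TxtS <- jaccard_matrix(SetM)

  # comorbidity: IC matrix over distinct codes, then mean over cross pairs
  code_sets <- lapply(patients, `[[`, "comorbidities")
  ucodes <- unique(unlist(code_sets, use.names = FALSE))
  if (length(ucodes)) {
    ICu <- matrix(0, length(ucodes), length(ucodes),
                  dimnames = list(ucodes, ucodes))
    for (i in seq_along(ucodes)) {
      for (j in i:length(ucodes)) {
        ICu[i, j] <- ICu[j, i] <- ic_pair(ucodes[i], ucodes[j], corpus)
      }
    }
    idx_sets <- lapply(code_sets, function(s) match(s, ucodes))
  } else {
    idx_sets <- lapply(code_sets, function(s) integer(0))
  }

  pairs <- index_pairs(n)
  np <- nrow(pairs)
  cm_raw <- numeric(np)
  for (k in seq_len(np)) {
    si <- idx_sets[[pairs[k, 1]]]
    sj <- idx_sets[[pairs[k, 2]]]
    cm_raw[k] <- if (length(si) == 0L && length(sj) == 0L) NA_real_
      else if (length(si) == 0L || length(sj) == 0L) 0
      else mean(ICu[si, sj, drop = FALSE])
  }
  finite <- cm_raw[!is.na(cm_raw)]
  cm_range <- if (length(finite)) range(finite) else c(0, 0)
  if (length(finite) && cm_range[1] == cm_range[2]) {
    warning("all pairs share the same raw comorbidity similarity; ",
            "component set to 0.5", call. = FALSE)
  }
  cm_norm <- normalize_comorbidity(cm_raw, cm_range)

  ut <- function(M) M[pairs]
  out <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                    age = ut(AgeS), sex = ut(SexS), drug_allergy = ut(AllS),
                    admission_source = ut(AdmS))
  for (j in seq_along(IndS)) out[[paste0("text_", j)]] <- ut(IndS[[j]])
  out$comorbidity <- cm_norm
  out$labs <- ut(LabS)
  out$text_set <- ut(TxtS)
  attr(out, "comorbidity_range") <- cm_range
  out
}

# pairwise Jaccard similarity between rows of a 0/1 matrix;
# two empty rows -> 1, one empty -> 0
jaccard_matrix <- function(M) {
  inter <- tcrossprod(M)
  sz <- rowSums(M)
  uni <- outer(sz, sz, "+") - inter
  J <- ifelse(uni > 0, inter / uni, 1)
  J
}
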