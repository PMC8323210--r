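#' EMR cohort objects
#'
#' A cohort is a list of de-identified hospitalization records. Each patient
#' record carries four demographic features (age in years, sex, drug-allergy
#' history, source of admission — all but age coded 0/1), a set of normalized
#' ICD-10 comorbidity codes, a named vector of laboratory results (raw values
#' or 0/1 abnormality flags) and a set of tokenized radiology-report phrases.
#' Latent disease-class labels, when known (synthetic cohorts or a labelled
#' study population), are stored alongside the records in `labels` and are
#' never consulted by any similarity computation — only by the prediction
#' evaluation harness.
#'
#' @param patients List of patient records, each a list with fields `id`,
#'   `age`, `sex`, `drug_allergy`, `admission_source`, `comorbidities`,
#'   `labs`, `report_tokens`.
#' @param labels Optional character vector of disease-class labels, one per
#'   patient, named by patient id.
#' @return An object of class `emr_cohort`.
#' @export
emr_cohort <- function(patients, labels = NULL) {
  if (!is.list(patients) || length(patients) == 0L) {
    stop("`patients` must be a non-empty list", call. = FALSE)
  }
  patients <- lapply(patients, validate_patient)
  ids <- vapply(patients, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate patient id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(patients) <- ids
  if (!is.null(labels)) {
    if (length(labels) != length(patients)) {
      stop("`labels` must have one entry per patient", call. = FALSE)
    }
    if (is.null(names(labels))) names(labels) <- ids
    labels <- labels[ids]
  }
  structure(list(patients = patients, labels = labels), class = "emr_cohort")
}

validate_patient <- function(p) {
  required <- c("id", "age", "sex", "drug_allergy", "admission_source",
                "comorbidities", "labs", "report_tokens")
  missing <- setdiff(required, names(p))
  if (length(missing)) {
    stop("patient record missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.character(p$id) || length(p$id) != 1L || !nzchar(p$id)) {
    stop("patient `id` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(p$age) || length(p$age) != 1L || is.na(p$age) || p$age < 0) {
    stop("patient `", p$id, "`: age must be a nonnegative number", call. = FALSE)
  }
  for (f in c("sex", "drug_allergy", "admission_source")) {
    if (!is_binary01(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]])) {
      stop("patient `", p$id, "`: `", f, "` must be 0 or 1", call. = FALSE)
    }
    p[[f]] <- as.numeric(p[[f]])
  }
  p$comorbidities <- as.character(p$comorbidities %||% character(0))
  if (length(p$comorbidities)) {
    ok <- grepl("^[A-Za-z][0-9]{0,3}$",
                gsub("\\.", "", p$comorbidities))
    if (!all(ok)) {
      stop("patient `", p$id, "`: malformed ICD-10 code(s): ",
           paste(p$comorbidities[!ok], collapse = ", "), call. = FALSE)
    }
  }
  labs <- unlist(p$labs)
  if (length(labs) && is.null(names(labs))) {
    stop("patient `", p$id, "`: labs must be named", call. = FALSE)
  }
  p$labs <- labs
  p$report_tokens <- as.character(p$report_tokens %||% character(0))
  p
}

#' @export
print.emr_cohort <- function(x, ...) {
  n <- length(x$patients)
  cat("EMR cohort:", n, "patients\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  nlab <- length(x$patients[[1]]$labs)
  cat("  features per patient:", nlab, "labs,",
      "comorbidities (median",
      stats::median(vapply(x$patients, function(p) length(p$comorbidities), 1L)),
      "codes), report tokens\n")
  invisible(x)
}

#' @rdname emr_cohort
#' @param cohort An `emr_cohort` object.
#' @export
cohort_ids <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  names(cohort$patients)
}

#' @rdname emr_cohort
#' @param ids Character vector of patient ids to keep (order preserved).
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "emr_cohort"))
  bad <- setdiff(ids, cohort_ids(cohort))
  if (length(bad)) stop("unknown patient id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  emr_cohort(cohort$patients[ids],
             labels = if (!is.null(cohort$labels)) cohort$labels[ids])
}

#' Normalize an ICD-10 code
#'
#' ICD-10 codes are simplified to a leading letter plus at most three digits:
#' the dot is removed, the code is truncated after the third digit and
#' upper-cased. The transformation is idempotent.
#'
#' @param code Character vector of ICD-10 codes (each must begin with a letter).
#' @return Character vector of normalized codes.
#' @examples
#' normalize_icd(c("C78.7", "K76.0", "K269"))  # "C787" "K760" "K269"
#' @export
normalize_icd <- function(code) {
  if (!is.character(code) || any(is.na(code)) || any(!nzchar(code))) {
    stop("codes must be non-empty strings", call. = FALSE)
  }
  x <- toupper(gsub(".", "", code, fixed = TRUE))
  if (any(!grepl("^[A-Z]", x))) {
    stop("ICD-10 code must begin with a letter: ",
         paste(code[!grepl("^[A-Z]", x)], collapse = ", "), call. = FALSE)
  }
  if (any(!grepl("^[A-Z][0-9]*$", x))) {
    stop("ICD-10 code must be a letter followed by digits: ",
         paste(code[!grepl("^[A-Z][0-9]*$", x)], collapse = ", "), call. = FALSE)
  }
  substr(x, 1L, 4L)
}

#' Remove outcome-defining codes from comorbidity lists
#'
#' Codes used to define the prediction outcome (for the liver-condition task:
#' C22 liver cancer, C78.7 secondary liver malignancy, D18.0 hemangioma,
#' K76.0 NAFLD) must not leak into the similarity features. A patient code is
#' dropped when it equals an outcome code or extends it (e.g. `C220` under
#' `C22`).
#'
#' @param cohort An `emr_cohort`.
#' @param codes Outcome ICD-10 codes (normalized internally).
#' @return The cohort with matching comorbidity codes removed.
#' @export
exclude_outcome_codes <- function(cohort,
                                  codes = c("C22", "C78.7", "D18.0", "K76.0")) {
  stopifnot(inherits(cohort, "emr_cohort"))
  codes <- normalize_icd(codes)
  cohort$patients <- lapply(cohort$patients, function(p) {
    cm <- normalize_icd2(p$comorbidities)
    keep <- !vapply(cm, function(x) {
      any(startsWith(x, codes))
    }, logical(1))
    p$comorbidities <- unname(cm[keep])
    p
  })
  cohort
}

# normalize a possibly-empty code vector
normalize_icd2 <- function(x) {
  if (length(x) == 0L) return(character(0))
  normalize_icd(x)
}

#' Binarize laboratory results against normal ranges
#'
#' Each laboratory value is recoded to 0 (normal) when it lies inside the
#' closed interval `[low, high]` of its normal range and 1 (abnormal)
#' otherwise. Values already coded 0/1 pass through unchanged. Missing values
#' must be imputed first (see [impute_missing()]).
#'
#' @param cohort An `emr_cohort`.
#' @param ranges Data frame with columns `test`, `low`, `high` (`low <= high`);
#'   may be `NULL` when all labs are already 0/1.
#' @return The cohort with all lab values in \{0, 1\}.
#' @export
binarize_labs <- function(cohort, ranges = NULL) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!is.null(ranges)) {
    if (!all(c("test", "low", "high") %in% names(ranges))) {
      stop("`ranges` needs columns test, low, high", call. = FALSE)
    }
    if (any(ranges$low > ranges$high)) {
      stop("normal range with low > high", call. = FALSE)
    }
    lows <- stats::setNames(ranges$low, ranges$test)
    highs <- stats::setNames(ranges$high, ranges$test)
  }
  cohort$patients <- lapply(cohort$patients, function(p) {
    v <- p$labs
    if (anyNA(v)) {
      stop("patient `", p$id,
           "` has missing lab values; run impute_missing() first",
           call. = FALSE)
    }
    # tests with a supplied range are binarized by it; the rest must already
    # be coded 0/1 and pass through
    has_range <- names(v) %in% if (is.null(ranges)) character(0) else ranges$test
    bare <- v[!has_range]
    if (length(bare) && !is_binary01(bare)) {
      stop("no normal range for non-binary lab test(s): ",
           paste(names(bare)[!bare %in% c(0, 1)], collapse = ", "),
           call. = FALSE)
    }
    idx <- which(has_range)
    if (length(idx)) {
      v[idx] <- as.numeric(!(v[idx] >= lows[names(v)[idx]] &
                               v[idx] <= highs[names(v)[idx]]))
      p$labs <- v
    }
    p
  })
  cohort
}

#' Impute missing laboratory values with decision trees
#'
#' For each laboratory feature with missing entries, a single CART tree
#' (regression for continuous values, classification for 0/1 values) is fitted
#' on the complete cases, using all other laboratory features plus the four
#' demographic features as predictors, and the fitted tree predicts the
#' missing entries. Trees use the standard variance-reduction / Gini split
#' criteria with a minimum leaf size of 5 and are deterministic given cohort
#' order.
#'
#' @param cohort An `emr_cohort` whose patients share the same lab panel.
#' @return The cohort with no missing lab values.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "emr_cohort"))
  ids <- cohort_ids(cohort)
  labnames <- names(cohort$patients[[1]]$labs)
  L <- do.call(rbind, lapply(cohort$patients, function(p) p$labs[labnames]))
  if (!anyNA(L)) return(cohort)
  demo <- data.frame(
    age = vapply(cohort$patients, `[[`, numeric(1), "age"),
    sex = vapply(cohort$patients, `[[`, numeric(1), "sex"),
    drug_allergy = vapply(cohort$patients, `[[`, numeric(1), "drug_allergy"),
    admission_source = vapply(cohort$patients, `[[`, numeric(1),
                              "admission_source")
  )
  all_missing <- colSums(!is.na(L)) == 0L
  if (any(all_missing)) {
    stop("lab feature(s) missing for every patient, cannot impute: ",
         paste(labnames[all_missing], collapse = ", "), call. = FALSE)
  }
  ctrl <- rpart::rpart.control(minsplit = 10, minbucket = 5, cp = 0.01,
                               xval = 0)
  filled <- L
  for (j in which(colSums(is.na(L)) > 0L)) {
    y <- L[, j]
    miss <- is.na(y)
    # predictors: observed values of the other labs + demographics
    X <- cbind(as.data.frame(L[, -j, drop = FALSE]), demo)
    if (length(unique(y[!miss])) == 1L) {
      filled[miss, j] <- y[!miss][1]   # constant among complete cases
      next
    }
    dat <- cbind(.y = y, X)
    binary <- is_binary01(y)
    if (binary) dat$.y <- factor(dat$.y, levels = c(0, 1))
    fit <- rpart::rpart(.y ~ ., data = dat[!miss, , drop = FALSE],
                        method = if (binary) "class" else "anova",
                        control = ctrl)
    pred <- if (binary) {
      as.numeric(as.character(
        stats::predict(fit, newdata = dat[miss, , drop = FALSE], type = "class")))
    } else {
      as.numeric(stats::predict(fit, newdata = dat[miss, , drop = FALSE]))
    }
    filled[miss, j] <- pred
  }
  for (i in seq_along(ids)) {
    cohort$patients[[i]]$labs <- stats::setNames(filled[i, ], labnames)
  }
  cohort
}

#' Popular comorbidities of a cohort
#'
#' Returns the ICD-10 codes whose patient-level occurrence fraction is
#' strictly greater than `threshold` (the "greater than 5%" rule yields the
#' binary comorbidity features of the Euclidean patient representation),
#' sorted by descending frequency and then lexicographically.
#'
#' @param cohort An `emr_cohort`.
#' @param threshold Occurrence fraction in `[0, 1)`; default 0.05.
#' @return Character vector of normalized codes.
#' @export
select_popular_comorbidities <- function(cohort, threshold = 0.05) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  }
  n <- length(cohort$patients)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  counts <- table(unlist(lapply(cohort$patients,
                                function(p) unique(p$comorbidities))))
  frac <- as.numeric(counts) / n
  keep <- frac > threshold
  codes <- names(counts)[keep]
  frac <- frac[keep]
  codes[order(-frac, codes)]
}

#' Assemble the numeric (Euclidean) patient representation
#'
#' Builds, per patient, the flat 0/1-dominated feature vector used wherever a
#' Euclidean distance is needed: report-phrase indicator columns (independent
#' phrases first, then set phrases), binarized lab columns, popular-comorbidity
#' indicator columns, and the four demographic features. With the reference
#' group sizes 44 text + 57 labs + 26 comorbidities + 4 demographics the
#' vector has 131 features. Age is min-max scaled to `[0, 1]` over the cohort
#' so the single continuous feature does not dominate distances.
#'
#' @param cohort An `emr_cohort` with binarized labs.
#' @param popular Character vector of popular comorbidity codes (see
#'   [select_popular_comorbidities()]); each must occur in the cohort.
#' @param schema A [text_schema()] describing the report-phrase features.
#' @return Numeric matrix (patients x features) with named columns and an
#'   attribute `schema`: a data frame mapping each column to its feature group.
#' @export
assemble_numeric <- function(cohort, popular, schema) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(schema, "text_schema"))
  ids <- cohort_ids(cohort)
  all_codes <- unique(unlist(lapply(cohort$patients, `[[`, "comorbidities")))
  unknown <- setdiff(popular, all_codes)
  if (length(unknown)) {
    stop("popular comorbidity code(s) absent from cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  labnames <- names(cohort$patients[[1]]$labs)
  labs <- do.call(rbind, lapply(cohort$patients, function(p) {
    v <- p$labs[labnames]
    if (anyNA(v) || !is_binary01(v)) {
      stop("labs must be binarized (0/1, no missing) before assembly",
           call. = FALSE)
    }
    v
  }))
  phrases <- c(schema$independent, schema$set)
  tokens <- lapply(cohort$patients, `[[`, "report_tokens")
  text <- presence_matrix(tokens, phrases)
  cm <- presence_matrix(lapply(cohort$patients, `[[`, "comorbidities"),
                        popular)
  age <- vapply(cohort$patients, `[[`, numeric(1), "age")
  rng <- range(age)
  age_scaled <- if (rng[2] > rng[1]) (age - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(age))
  demo <- cbind(age = age_scaled,
                sex = vapply(cohort$patients, `[[`, numeric(1), "sex"),
                drug_allergy = vapply(cohort$patients, `[[`, numeric(1),
                                      "drug_allergy"),
                admission_source = vapply(cohort$patients, `[[`, numeric(1),
                                          "admission_source"))
  X <- cbind(text, labs, cm, demo)
  rownames(X) <- ids
  attr(X, "schema") <- data.frame(
    column = colnames(X),
    group = rep(c("text", "lab", "comorbidity", "demographic"),
                c(ncol(text), ncol(labs), ncol(cm), 4L))
  )
  X
}
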