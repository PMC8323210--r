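#' Read and write EMR cohorts
#'
#' Cohorts are serialized either as JSON-lines (one patient object per line,
#' the lossless interchange format) or as a flat CSV in which the comorbidity
#' and report-token sets are `;`-joined strings and each laboratory test is a
#' `lab_<name>` column. Writing then reading a cohort reproduces it exactly.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; inferred from the file extension when
#'   missing.
#' @return `read_cohort()` returns an `emr_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "jsonl") read_cohort_jsonl(path) else read_cohort_csv(path)
}

#' @rdname read_cohort
#' @param cohort An `emr_cohort`.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(cohort, "emr_cohort"))
  format <- resolve_format(match.arg(format), path)
  if (format == "jsonl") write_cohort_jsonl(cohort, path) else
    write_cohort_csv(cohort, path)
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json", "ndjson")) "jsonl"
  else if (ext == "csv") "csv"
  else stop("cannot infer format from extension `.", ext,
            "`; pass format=", call. = FALSE)
}

required_patient_fields <- c("id", "age", "sex", "drug_allergy",
                             "admission_source", "comorbidities", "labs",
                             "report_tokens")

read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty cohort file: ", path, call. = FALSE)
  labels <- character(0)
  patients <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("parse error at line ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    missing <- setdiff(required_patient_fields, names(rec))
    if (length(missing)) {
      stop("parse error at line ", i, ": missing field(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    rec$labs <- unlist(rec$labs)
    if (!is.null(rec$label)) {
      labels[rec$id] <- rec$label
      rec$label <- NULL
    }
    patients[[i]] <- rec
  }
  emr_cohort(patients, labels = if (length(labels)) labels)
}

write_cohort_jsonl <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in cohort$patients) {
    rec <- p[required_patient_fields]
    rec$comorbidities <- as.list(rec$comorbidities)
    rec$report_tokens <- as.list(rec$report_tokens)
    rec$labs <- as.list(rec$labs)
    if (!is.null(cohort$labels)) rec$label <- unname(cohort$labels[p$id])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
}

read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  labcols <- grep("^lab_", names(df), value = TRUE)
  patients <- lapply(seq_len(nrow(df)), function(i) {
    labs <- as.numeric(df[i, labcols])
    names(labs) <- sub("^lab_", "", labcols)
    list(id = df$id[i], age = df$age[i], sex = df$sex[i],
         drug_allergy = df$drug_allergy[i],
         admission_source = df$admission_source[i],
         comorbidities = split_set(df$comorbidities[i]),
         labs = labs,
         report_tokens = split_set(df$report_tokens[i]))
  })
  labels <- if ("label" %in% names(df)) stats::setNames(df$label, df$id)
  emr_cohort(patients, labels = labels)
}

write_cohort_csv <- function(cohort, path) {
  labnames <- names(cohort$patients[[1]]$labs)
  df <- data.frame(
    id = cohort_ids(cohort),
    age = vapply(cohort$patients, `[[`, numeric(1), "age"),
    sex = vapply(cohort$patients, `[[`, numeric(1), "sex"),
    drug_allergy = vapply(cohort$patients, `[[`, numeric(1), "drug_allergy"),
    admission_source = vapply(cohort$patients, `[[`, numeric(1),
                              "admission_source"),
    comorbidities = vapply(cohort$patients,
                           function(p) paste(p$comorbidities, collapse = ";"),
                           character(1)),
    report_tokens = vapply(cohort$patients,
                           function(p) paste(p$report_tokens, collapse = ";"),
                           character(1)),
    check.names = FALSE
  )
  labs <- do.call(rbind, lapply(cohort$patients, function(p) p$labs[labnames]))
  colnames(labs) <- paste0("lab_", labnames)
  df <- cbind(df, labs)
  if (!is.null(cohort$labels)) df$label <- unname(cohort$labels[df$id])
  utils::write.csv(df, path, row.names = FALSE)
}

split_set <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}
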