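test_that("ICD-10 normalization strips dots, truncates and upper-cases", {
  expect_equal(normalize_icd("C78.7"), "C787")
  expect_equal(normalize_icd("K76.0"), "K760")
  expect_equal(normalize_icd("K269"), "K269")          # idempotent
  expect_equal(normalize_icd(normalize_icd("e11.65")), "E116")
  expect_equal(normalize_icd("I10"), "I10")
  expect_error(normalize_icd(""), "non-empty")
  expect_error(normalize_icd("123"), "letter")
})

test_that("cohort IO round-trips in both formats", {
  cohort <- generate_cohort(cohort_config(n_patients = 30, seed = 3))
  for (fmt in c("jsonl", "csv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(cohort, path)
    back <- read_cohort(path)
    expect_length(back$patients, 30)
    expect_equal(cohort_ids(back), cohort_ids(cohort))
    expect_equal(back$labels, cohort$labels)
    for (id in cohort_ids(cohort)) {
      expect_equal(back$patients[[id]], cohort$patients[[id]])
    }
    # writing the re-read cohort reproduces the file contents
    path2 <- tempfile(fileext = paste0(".", fmt))
    write_cohort(back, path2)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("malformed cohort records are rejected with the offending line", {
  path <- tempfile(fileext = ".jsonl")
  cohort <- generate_cohort(cohort_config(n_patients = 4, seed = 1))
  write_cohort(cohort, path)
  lines <- readLines(path)
  rec <- jsonlite::fromJSON(lines[2])
  rec$age <- NULL
  lines[2] <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  writeLines(lines, path)
  expect_error(read_cohort(path), "line 2.*age")

  # duplicate id
  lines[2] <- lines[1]
  writeLines(lines, path)
  expect_error(read_cohort(path), "duplicate")
})

test_that("lab binarization uses a closed normal interval", {
  ranges <- data.frame(test = c("alt", "ast"), low = c(4, 10), high = c(6, 40))
  cohort <- emr_cohort(list(
    make_patient("P1", labs = c(alt = 5.0, ast = 50)),
    make_patient("P2", labs = c(alt = 7.0, ast = 4.0)),
    make_patient("P3", labs = c(alt = 4.0, ast = 40.0))  # both boundaries
  ))
  b <- binarize_labs(cohort, ranges)
  expect_equal(unname(b$patients$P1$labs), c(0, 1))
  expect_equal(unname(b$patients$P2$labs), c(1, 1))
  expect_equal(unname(b$patients$P3$labs), c(0, 0))
  # idempotent: binarizing again changes nothing
  expect_identical(binarize_labs(b, ranges), binarize_labs(b, ranges))
  expect_true(all(unlist(lapply(binarize_labs(b, ranges)$patients,
                                `[[`, "labs")) %in% 0:1))
})

test_that("binarization refuses missing values and unknown tests", {
  cohort <- emr_cohort(list(make_patient("P1", labs = c(alt = NA))))
  expect_error(binarize_labs(cohort), "impute")
  cohort2 <- emr_cohort(list(make_patient("P1", labs = c(alt = 7))))
  expect_error(binarize_labs(cohort2), "range")
})

test_that("tree imputation recovers a deterministic rule and constants", {
  # x2 equals x1 on complete cases; the masked entry with x1 = 0 must get 0
  n <- 21
  x1 <- rep(c(0, 1), length.out = n)
  labs <- lapply(seq_len(n), function(i) {
    c(x1 = x1[i], x2 = if (i == 1) NA else x1[i], x3 = 1)
  })
  cohort <- emr_cohort(lapply(seq_len(n), function(i) {
    make_patient(sprintf("P%02d", i), labs = labs[[i]])
  }))
  expect_equal(x1[1], 0)
  imp <- impute_missing(cohort)
  expect_equal(unname(imp$patients$P01$labs["x2"]), 0)
  # constant feature: x3 is 1 everywhere it is observed
  cohort$patients$P02$labs["x3"] <- NA
  imp2 <- impute_missing(cohort)
  expect_equal(unname(imp2$patients$P02$labs["x3"]), 1)
  expect_false(anyNA(unlist(lapply(imp2$patients, `[[`, "labs"))))
  # identity on complete cohorts
  complete <- generate_cohort(cohort_config(n_patients = 10, seed = 5))
  expect_identical(impute_missing(complete), complete)
})

test_that("imputation fails when a feature is never observed", {
  cohort <- emr_cohort(list(
    make_patient("P1", labs = c(a = NA, b = 1)),
    make_patient("P2", labs = c(a = NA, b = 0))
  ))
  expect_error(impute_missing(cohort), "cannot impute")
})

test_that("imputation then binarization leaves clean 0/1 labs", {
  cohort <- generate_cohort(cohort_config(n_patients = 40, seed = 6))
  masked <- inject_missingness(cohort, 0.15, seed = 2)
  clean <- binarize_labs(impute_missing(masked))
  labs <- unlist(lapply(clean$patients, `[[`, "labs"))
  expect_false(anyNA(labs))
  expect_true(all(labs %in% 0:1))
})

test_that("popular comorbidities use a strict occurrence threshold", {
  patients <- lapply(1:100, function(i) {
    codes <- character(0)
    if (i <= 6) codes <- c(codes, "A100")   # 6% -> kept at 0.05
    if (i <= 5) codes <- c(codes, "B200")   # exactly 5% -> dropped
    if (i <= 40) codes <- c(codes, "C300")  # most frequent
    make_patient(sprintf("P%03d", i), codes = codes)
  })
  cohort <- emr_cohort(patients)
  pop <- select_popular_comorbidities(cohort, 0.05)
  expect_equal(pop, c("C300", "A100"))
  # threshold 0 keeps everything, ordered by frequency then code
  expect_equal(select_popular_comorbidities(cohort, 0),
               c("C300", "A100", "B200"))
  expect_error(select_popular_comorbidities(cohort, 1), "threshold")
})

test_that("outcome codes (and their extensions) are excluded", {
  cohort <- emr_cohort(list(
    make_patient("P1", codes = c("C220", "C787", "K760", "I10")),
    make_patient("P2", codes = c("D180", "K761"))
  ))
  out <- exclude_outcome_codes(cohort)
  expect_equal(out$patients$P1$comorbidities, "I10")
  expect_equal(out$patients$P2$comorbidities, "K761")  # K761 != K760
})

test_that("numeric representation has the documented layout", {
  cohort <- binarize_labs(generate_cohort(cohort_config(30, seed = 9)))
  cohort <- exclude_outcome_codes(cohort)
  schema <- pipeline_schema(cohort)
  popular <- select_popular_comorbidities(cohort, 0.05)
  X <- assemble_numeric(cohort, popular, schema)
  expect_equal(nrow(X), 30)
  sch <- attr(X, "schema")
  expect_equal(ncol(X), nrow(sch))
  expect_equal(unname(table(sch$group)[c("text", "lab", "comorbidity",
                                         "demographic")]),
               c(length(schema$independent) + length(schema$set), 57L,
                 length(popular), 4L), ignore_attr = TRUE)
  # all but age are binary; age scaled into [0, 1]
  expect_true(all(X[, sch$group != "demographic"] %in% 0:1))
  expect_true(all(X[, "age"] >= 0 & X[, "age"] <= 1))
  # identical patients map to identical vectors
  i <- cohort_ids(cohort)[1]
  expect_equal(unname(X[i, ]), unname(X[i, ]))
  # permutation stability: shuffling patients permutes rows only
  ord <- rev(cohort_ids(cohort))
  X2 <- assemble_numeric(subset_cohort(cohort, ord), popular, schema)
  expect_equal(X2[cohort_ids(cohort), ], X[cohort_ids(cohort), ])
  expect_error(assemble_numeric(cohort, c(popular, "Z999"), schema),
               "absent")
})
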