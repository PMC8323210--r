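test_that("fragment corpus counts every prefix of every code occurrence", {
  corpus <- build_fragment_corpus(micro_corpus_cohort())
  expect_equal(corpus$total, 12)
  expect_equal(unname(corpus$counts["K"]), 3L)
  expect_equal(unname(corpus$counts["K2"]), 2L)
  expect_equal(unname(corpus$counts["K26"]), 1L)
  expect_equal(sum(corpus$counts), corpus$total)

  single <- emr_cohort(list(make_patient("X", codes = "A00")))
  c2 <- build_fragment_corpus(single)
  expect_equal(sort(names(c2$counts)), c("A", "A0", "A00"))
  expect_equal(c2$total, 3)

  empty <- emr_cohort(list(make_patient("X")))
  expect_error(build_fragment_corpus(empty), "no comorbidity")
})

test_that("a shorter fragment is never rarer than its extension", {
  cohort <- generate_cohort(cohort_config(n_patients = 60, seed = 10))
  corpus <- build_fragment_corpus(cohort)
  for (frag in names(corpus$counts)) {
    if (nchar(frag) > 1) {
      parent <- substr(frag, 1, nchar(frag) - 1)
      expect_gte(corpus$counts[parent], corpus$counts[frag])
    }
  }
})

test_that("IC of a code pair matches the hand-enumerated micro-corpus", {
  corpus <- build_fragment_corpus(micro_corpus_cohort())
  expect_equal(ic_pair("K269", "K293", corpus), -log(2 / 12))
  expect_equal(ic_pair("K269", "K761", corpus), -log(3 / 12))
  # different leading letters share no information
  expect_equal(ic_pair("K269", "E116", corpus), 0)
  # IC is monotone in prefix length: the corpus count can only shrink
  expect_gte(ic_pair("K269", "K293", corpus), ic_pair("K269", "K761", corpus))
  expect_error(ic_pair("Z999", "Z998", corpus), "mismatch")
})

test_that("comorbidity similarity averages IC over all cross pairs", {
  corpus <- build_fragment_corpus(micro_corpus_cohort())
  expect_equal(comorbidity_similarity(c("K269", "K293"), "K761", corpus),
               -log(3 / 12))
  expect_equal(comorbidity_similarity("A00", "B00",
                                      build_fragment_corpus(emr_cohort(list(
                                        make_patient("X", codes = c("A00", "B00")))))),
               0)
  single <- build_fragment_corpus(emr_cohort(list(
    make_patient("X", codes = "K269"))))
  expect_equal(comorbidity_similarity("K269", "K269", single), -log(1 / 4))
  expect_equal(comorbidity_similarity(character(0), "K269", corpus), 0)
  expect_true(is.na(comorbidity_similarity(character(0), character(0), corpus)))
})

test_that("elementary similarities follow their formulas", {
  expect_equal(binary_similarity(1, 1), 1)
  expect_equal(binary_similarity(0, 1), 0)
  expect_equal(binary_similarity(0, 0), 1)
  expect_error(binary_similarity(2, 0), "0/1")

  expect_equal(jaccard_set_similarity(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard_set_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_set_similarity(character(0), character(0)), 1)
  expect_equal(jaccard_set_similarity(character(0), "a"), 0)

  expect_equal(age_similarity(25, 50), 0.5)
  expect_equal(age_similarity(60, 60), 1)
  expect_equal(age_similarity(0, 40), 0)
  expect_equal(age_similarity(0, 0), 1)
  expect_error(age_similarity(-1, 5), "nonnegative")
})

test_that("the pair vector has 12 named components and full-similarity diagonal", {
  cohort <- toy_cohort()
  corpus <- build_fragment_corpus(cohort)
  schema <- toy_schema()
  v <- pair_similarity_vector(cohort$patients$P1, cohort$patients$P2,
                              corpus, schema)
  expect_length(v, 12)
  expect_named(v, similarity_components())
  # identical patients: every component 1 (comorbidity normalized to its max)
  raw_cm <- unname(pair_similarity_vector(cohort$patients$P1,
                                          cohort$patients$P1, corpus,
                                          schema)["comorbidity"])
  v_self <- pair_similarity_vector(cohort$patients$P1, cohort$patients$P1,
                                   corpus, schema,
                                   comorbidity_range = c(0, raw_cm))
  expect_equal(unname(v_self), rep(1, 12))
  # symmetry
  v_rev <- pair_similarity_vector(cohort$patients$P2, cohort$patients$P1,
                                  corpus, schema)
  expect_equal(v, v_rev)
})

test_that("the pairwise table matches brute-force recomputation on <= 5 patients", {
  cohort <- toy_cohort()
  schema <- toy_schema()
  tab <- pairwise_similarity_table(cohort, schema = schema)
  expect_equal(nrow(tab), choose(4, 2))
  expect_equal(tab$id_a, c("P1", "P1", "P1", "P2", "P2", "P3"))
  expect_equal(tab$id_b, c("P2", "P3", "P4", "P3", "P4", "P4"))
  expect_true(all(as.matrix(tab[similarity_components()]) >= 0))
  expect_true(all(as.matrix(tab[similarity_components()]) <= 1))

  # independent recomputation from the raw formulas
  all_codes <- unlist(lapply(cohort$patients, `[[`, "comorbidities"))
  cm_raw <- numeric(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    pi <- cohort$patients[[tab$id_a[k]]]
    pj <- cohort$patients[[tab$id_b[k]]]
    expect_equal(tab$age[k], min(pi$age, pj$age) / max(pi$age, pj$age))
    expect_equal(tab$sex[k], as.numeric(pi$sex == pj$sex))
    expect_equal(tab$drug_allergy[k],
                 as.numeric(pi$drug_allergy == pj$drug_allergy))
    expect_equal(tab$admission_source[k],
                 as.numeric(pi$admission_source == pj$admission_source))
    for (j in 1:5) {
      ph <- schema$independent[j]
      expect_equal(tab[[paste0("text_", j)]][k],
                   as.numeric((ph %in% pi$report_tokens) ==
                                (ph %in% pj$report_tokens)))
    }
    li <- names(pi$labs)[pi$labs == 1]
    lj <- names(pj$labs)[pj$labs == 1]
    expect_equal(tab$labs[k], jaccard_set_similarity(li, lj))
    si <- intersect(schema$set, pi$report_tokens)
    sj <- intersect(schema$set, pj$report_tokens)
    expect_equal(tab$text_set[k], jaccard_set_similarity(si, sj))
    ci <- pi$comorbidities
    cj <- pj$comorbidities
    cm_raw[k] <- if (!length(ci) && !length(cj)) NA else
      if (!length(ci) || !length(cj)) 0 else
        mean(outer(ci, cj, Vectorize(function(a, b) oracle_ic(a, b, all_codes))))
  }
  rng <- range(cm_raw, na.rm = TRUE)
  cm_norm <- (cm_raw - rng[1]) / (rng[2] - rng[1])
  cm_norm[is.na(cm_raw)] <- 1
  expect_equal(tab$comorbidity, cm_norm)
  # monotone rescaling preserves pair ordering
  expect_equal(order(tab$comorbidity[!is.na(cm_raw)]),
               order(cm_raw[!is.na(cm_raw)]))
})

test_that("pairwise table enumerates n(n-1)/2 canonical pairs", {
  cohort <- pipeline_cohort(8, seed = 2)
  schema <- pipeline_schema(cohort)
  tab <- pairwise_similarity_table(cohort, schema = schema)
  expect_equal(nrow(tab), choose(8, 2))
  expect_true(all(tab$id_a < tab$id_b))
  expect_false(any(duplicated(paste(tab$id_a, tab$id_b))))
  two <- suppressWarnings(
    pairwise_similarity_table(subset_cohort(cohort, cohort_ids(cohort)[1:2]),
                              corpus = build_fragment_corpus(cohort),
                              schema = schema))
  expect_equal(nrow(two), 1)
  expect_error(pairwise_similarity_table(
    subset_cohort(cohort, cohort_ids(cohort)[1]), schema = schema), "2")
})
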