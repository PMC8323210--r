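# hand-built fixtures and independent oracles used across test files

make_patient <- function(id, age = 50, sex = 1, allergy = 0, admission = 1,
                         codes = character(0),
                         labs = c(alt = 0, ast = 0, ggt = 0),
                         tokens = character(0)) {
  list(id = id, age = age, sex = sex, drug_allergy = allergy,
       admission_source = admission, comorbidities = codes, labs = labs,
       report_tokens = tokens)
}

# three patients, one ICD code each: the micro-corpus used for hand-checked
# IC values (12 fragments: K x3, K2 x2, K26, K269, K29, K293, K7, K76, K761)
micro_corpus_cohort <- function() {
  emr_cohort(list(
    make_patient("A", codes = "K269"),
    make_patient("B", codes = "K293"),
    make_patient("C", codes = "K761")
  ))
}

toy_schema <- function() {
  text_schema(independent = paste0("ip", 1:5),
              set = paste0("sp", 1:6))
}

# small mixed cohort exercising every similarity component
toy_cohort <- function() {
  emr_cohort(list(
    make_patient("P1", age = 40, sex = 1, allergy = 0, admission = 1,
                 codes = c("K269", "K293"),
                 labs = c(alt = 1, ast = 0, ggt = 1),
                 tokens = c("ip1", "ip3", "sp1", "sp2")),
    make_patient("P2", age = 60, sex = 1, allergy = 1, admission = 1,
                 codes = "K761",
                 labs = c(alt = 1, ast = 1, ggt = 0),
                 tokens = c("ip1", "sp2", "sp3")),
    make_patient("P3", age = 30, sex = 0, allergy = 0, admission = 0,
                 codes = c("E116", "K269"),
                 labs = c(alt = 0, ast = 0, ggt = 0),
                 tokens = c("ip2", "sp4")),
    make_patient("P4", age = 40, sex = 1, allergy = 0, admission = 1,
                 codes = character(0),
                 labs = c(alt = 0, ast = 1, ggt = 1),
                 tokens = character(0))
  ))
}

# --- independent oracles -----------------------------------------------------

# fragment-corpus IC from first principles (string prefixes + counting)
oracle_ic <- function(c1, c2, all_codes) {
  frags <- unlist(lapply(all_codes,
                         function(x) substring(x, 1, seq_len(nchar(x)))))
  k <- 0
  while (k < min(nchar(c1), nchar(c2)) &&
         substr(c1, k + 1, k + 1) == substr(c2, k + 1, k + 1)) k <- k + 1
  if (k == 0) return(0)
  nca <- substr(c1, 1, k)
  -log(sum(frags == nca) / length(frags))
}

# brute-force scatter over all unordered sample pairs
oracle_scatter <- function(V, cls) {
  d <- ncol(V)
  Sw <- Sb <- matrix(0, d, d)
  for (p in seq_len(nrow(V) - 1)) {
    for (q in (p + 1):nrow(V)) {
      delta <- V[p, ] - V[q, ]
      O <- tcrossprod(delta)
      if (cls[p] == cls[q]) Sw <- Sw + O else Sb <- Sb + O
    }
  }
  list(S_w = Sw, S_b = Sb)
}

# dense grid search over unit vectors for the r = 1 trace quotient minimum
oracle_grid_quotient <- function(Sw, Sb, step_deg = 0.25) {
  d <- nrow(Sw)
  quot <- function(U) {
    num <- rowSums((U %*% Sw) * U)
    den <- rowSums((U %*% Sb) * U)
    num / den
  }
  if (d == 2) {
    th <- seq(0, pi, by = step_deg * pi / 180)
    U <- cbind(cos(th), sin(th))
  } else if (d == 3) {
    th <- seq(0, pi, by = step_deg * pi / 180)
    ph <- seq(0, pi, by = step_deg * pi / 180)
    g <- expand.grid(th = th, ph = ph)
    U <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  } else {
    stop("grid oracle only for d <= 3")
  }
  min(quot(U))
}

# exhaustive concordant-pair AUC (ties count 1/2)
oracle_auc <- function(scores, pos) {
  ps <- scores[pos]
  ns <- scores[!pos]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(ps) * length(ns))
}

# seeded random PSD matrix
random_psd <- function(d, seed) {
  set.seed(seed)
  M <- matrix(rnorm(d * d), d)
  crossprod(M) + diag(d) * 0.1
}

# standard preprocessed synthetic cohort for pipeline-level tests
pipeline_cohort <- function(n, seed) {
  exclude_outcome_codes(generate_cohort(cohort_config(n_patients = n,
                                                      seed = seed)))
}

pipeline_schema <- function(cohort) {
  build_text_schema(cohort, independent = independent_phrases())
}
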