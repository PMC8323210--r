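#' Synthetic EMR cohort configuration
#'
#' Configures the generator that emulates the study population: a liver-CT
#' inpatient cohort with four latent conditions (liver cancer, hemangioma,
#' NAFLD, normal) whose demographics, comorbidity codes, binary laboratory
#' abnormalities and report phrases differ by class. Defaults reproduce the
#' reference cohort's class mix and per-class demographic rates; the ICD-10
#' pool combines common comorbidities shared across classes with rare
#' class-specific code families that carry hierarchical (shared-prefix)
#' signal.
#'
#' @param n_patients Number of patients (>= 4).
#' @param class_proportions Fractions over the four classes
#'   (cancer, hemangioma, NAFLD, normal); must sum to 1.
#' @param n_lab_features Number of binary laboratory features (default 57).
#' @param n_text_set_features Number of set-type report phrases (default 39).
#' @param n_independent_text_features Number of independent report phrases
#'   (default 5).
#' @param icd_pool Data frame with column `code` and one prevalence column
#'   per class (`cancer`, `hemangioma`, `NAFLD`, `normal`), all rates in
#'   `[0, 1]`; default [default_icd_pool()].
#' @param lab_abnormal_rates Per-class abnormality probabilities: either one
#'   rate per class (recycled over labs) or a 4 x `n_lab_features` matrix.
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          class_proportions = c(cancer = 153, hemangioma = 178,
                                                NAFLD = 403, normal = 449) / 1183,
                          n_lab_features = 57L,
                          n_text_set_features = 39L,
                          n_independent_text_features = 5L,
                          icd_pool = default_icd_pool(),
                          lab_abnormal_rates = c(cancer = 0.12,
                                                 hemangioma = 0.10,
                                                 NAFLD = 0.12, normal = 0.08),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 4) {
    stop("`n_patients` must be an integer >= 4", call. = FALSE)
  }
  classes <- c("cancer", "hemangioma", "NAFLD", "normal")
  if (length(class_proportions) != 4L ||
      abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    stop("`class_proportions` must be 4 nonnegative fractions summing to 1",
         call. = FALSE)
  }
  names(class_proportions) <- classes
  if (!is.data.frame(icd_pool) || nrow(icd_pool) == 0L ||
      !all(c("code", classes) %in% names(icd_pool))) {
    stop("`icd_pool` must be a non-empty data frame with columns code, ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  assert_probability(unlist(icd_pool[classes]), "icd_pool prevalences")
  stopifnot(n_lab_features >= 1, n_text_set_features >= 1,
            n_independent_text_features >= 1)
  if (is.matrix(lab_abnormal_rates)) {
    stopifnot(nrow(lab_abnormal_rates) == 4L,
              ncol(lab_abnormal_rates) == n_lab_features)
  } else {
    stopifnot(length(lab_abnormal_rates) == 4L)
    lab_abnormal_rates <- matrix(rep(lab_abnormal_rates, n_lab_features),
                                 nrow = 4L,
                                 dimnames = list(classes, NULL))
  }
  assert_probability(lab_abnormal_rates, "lab_abnormal_rates")
  structure(list(n_patients = as.integer(n_patients),
                 classes = classes,
                 class_proportions = class_proportions,
                 n_lab_features = as.integer(n_lab_features),
                 n_text_set_features = as.integer(n_text_set_features),
                 n_independent_text_features =
                   as.integer(n_independent_text_features),
                 icd_pool = icd_pool,
                 lab_abnormal_rates = lab_abnormal_rates,
                 age_mean = c(cancer = 66.6, hemangioma = 57.2,
                              NAFLD = 51.4, normal = 51.8),
                 age_sd = c(cancer = 11.5, hemangioma = 11.3,
                            NAFLD = 13.7, normal = 13.3),
                 p_male = c(cancer = 0.660, hemangioma = 0.478,
                            NAFLD = 0.578, normal = 0.508),
                 p_allergy = c(cancer = 0.085, hemangioma = 0.129,
                               NAFLD = 0.199, normal = 0.129),
                 p_outpatient = c(cancer = 0.850, hemangioma = 0.921,
                                  NAFLD = 0.797, normal = 0.906),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default ICD-10 comorbidity pool
#'
#' Common comorbidities (coronary heart disease, diabetes with/without
#' complication, essential hypertension, lipid disorders, gastrointestinal
#' disorders, and a handful of background codes) occur in all classes at the
#' reference cohort's per-class rates and therefore end up among the
#' "popular" binary comorbidity features. Each class additionally draws from
#' a rare code family sharing a three-character prefix (e.g. chronic viral
#' hepatitis B18x for the cancer class), whose individual codes stay below
#' the popularity threshold: their class signal is visible to the
#' hierarchical IC similarity but largely invisible to the flat Euclidean
#' representation.
#'
#' @return Data frame with columns `code`, `cancer`, `hemangioma`, `NAFLD`,
#'   `normal`.
#' @export
default_icd_pool <- function() {
  common <- data.frame(
    code = c("I251", "E119", "E112", "I10", "E785", "K590",
             "K219", "N390", "J069", "M545"),
    cancer     = c(0.085, 0.183, 0.046, 0.399, 0.020, 0.150,
                   0.10, 0.06, 0.08, 0.07),
    hemangioma = c(0.056, 0.101, 0.045, 0.343, 0.118, 0.174,
                   0.10, 0.06, 0.08, 0.07),
    NAFLD      = c(0.067, 0.223, 0.109, 0.419, 0.335, 0.151,
                   0.10, 0.06, 0.08, 0.07),
    normal     = c(0.069, 0.127, 0.047, 0.258, 0.158, 0.149,
                   0.10, 0.06, 0.08, 0.07)
  )
  fam <- list(
    cancer = c(paste0("B18", c(0, 1, 2, 8, 9)), paste0("K74", c(0, 2, 6))),
    hemangioma = c(paste0("D35", c(0, 1, 2, 7, 9)), paste0("L98", c(0, 1, 9))),
    NAFLD = c(paste0("E66", c(0, 1, 2, 8, 9)), paste0("M79", c(1, 6, 7))),
    normal = c(paste0("J30", c(1, 2, 3, 4)), paste0("H52", c(0, 1, 2, 4)))
  )
  rare <- do.call(rbind, lapply(names(fam), function(cl) {
    df <- data.frame(code = fam[[cl]], cancer = 0.005, hemangioma = 0.005,
                     NAFLD = 0.005, normal = 0.005)
    df[[cl]] <- 0.12
    df
  }))
  rbind(common, rare)
}

#' Independent report phrases of the synthetic vocabulary
#'
#' The five clinically decisive phrases the synthetic generator plants in
#' reports (mirroring the kind of radiologist-nominated phrases — arterial
#' phase, lymph-node enlargement, parenchymal density — that become
#' independent binary features).
#'
#' @return Character vector of 5 phrases.
#' @export
independent_phrases <- function() {
  c("arterial phase enhancement", "retroperitoneal lymph node enlargement",
    "lower density than spleen", "absence of abnormal density",
    "uniform liver parenchyma")
}

#' Generate a synthetic EMR cohort
#'
#' Draws `n_patients` records: a latent class per patient (multinomial on the
#' configured proportions), class-conditional age (normal, truncated to
#' `[18, 95]`, rounded to whole years), binary demographics, 1-11 ICD-10
#' comorbidity codes (independent draws from the pool at class prevalences,
#' forced non-empty, truncated at 11), binary laboratory abnormalities, and
#' report tokens (independent + set phrases at class-conditional rates, with
#' occasional within-report repetition so term frequencies vary). The latent
#' class labels are returned in the cohort's `labels` field for the
#' evaluation harness only; no similarity computation reads them.
#'
#' @param config A [cohort_config()].
#' @return An `emr_cohort` with `labels`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    n <- config$n_patients
    classes <- config$classes
    cls <- sample(classes, n, replace = TRUE, prob = config$class_proportions)
    width <- max(3L, nchar(as.character(n)))
    ids <- sprintf(paste0("P%0", width, "d"), seq_len(n))
    labnames <- sprintf("lab_%02d", seq_len(config$n_lab_features))
    set_phr <- sprintf("finding_%02d", seq_len(config$n_text_set_features))
    ind_phr <- independent_phrases()[seq_len(
      min(5L, config$n_independent_text_features))]
    if (config$n_independent_text_features > 5L) {
      ind_phr <- c(ind_phr,
                   sprintf("impression_%02d",
                           seq_len(config$n_independent_text_features - 5L)))
    }
    # class-conditional phrase probabilities
    p_ind <- rbind(
      cancer     = c(0.70, 0.50, 0.60, 0.05, 0.10),
      hemangioma = c(0.60, 0.10, 0.40, 0.30, 0.30),
      NAFLD      = c(0.10, 0.05, 0.70, 0.20, 0.30),
      normal     = c(0.05, 0.05, 0.05, 0.80, 0.70)
    )
    p_ind <- p_ind[, seq_len(min(5L, length(ind_phr))), drop = FALSE]
    if (length(ind_phr) > ncol(p_ind)) {
      p_ind <- cbind(p_ind, matrix(0.2, 4L, length(ind_phr) - ncol(p_ind)))
    }
    n_set <- length(set_phr)
    block <- split(seq_len(n_set),
                   cut(seq_len(n_set), breaks = 4L, labels = classes))
    p_set <- matrix(0.06, 4L, n_set, dimnames = list(classes, NULL))
    for (cl in classes) p_set[cl, block[[cl]]] <- 0.30

    pool <- config$icd_pool
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- cls[i]
      age <- round(min(95, max(18, stats::rnorm(1, config$age_mean[cl],
                                                config$age_sd[cl]))))
      prev <- pool[[cl]]
      draw <- stats::runif(nrow(pool)) < prev
      codes <- pool$code[draw]
      if (length(codes) == 0L) {
        codes <- sample(pool$code, 1L, prob = prev + 1e-9)
      }
      if (length(codes) > 11L) codes <- sort(sample(codes, 11L))
      labs <- as.numeric(stats::runif(length(labnames)) <
                           config$lab_abnormal_rates[cl, ])
      tok_ind <- ind_phr[stats::runif(length(ind_phr)) < p_ind[cl, ]]
      tok_set <- set_phr[stats::runif(n_set) < p_set[cl, ]]
      toks <- c(tok_ind, tok_set)
      # repeat ~30% of tokens once so raw term frequencies are informative
      if (length(toks)) {
        toks <- c(toks, toks[stats::runif(length(toks)) < 0.3])
      }
      patients[[i]] <- list(
        id = ids[i], age = age,
        sex = as.numeric(stats::runif(1) < config$p_male[cl]),
        drug_allergy = as.numeric(stats::runif(1) < config$p_allergy[cl]),
        admission_source = as.numeric(stats::runif(1) < config$p_outpatient[cl]),
        comorbidities = sort(unique(normalize_icd(codes))),
        labs = stats::setNames(labs, labnames),
        report_tokens = toks
      )
    }
    emr_cohort(patients, labels = stats::setNames(cls, ids))
  })
}

#' Expert-score oracle configuration
#'
#' The synthetic stand-in for the domain expert: a pair's similarity score is
#' a fixed weighted sum of its 12 feature similarities plus Gaussian noise,
#' clipped to `[0, 1]`. Default weights concentrate 0.6 of their mass on the
#' three set-valued components (comorbidity, labs, text set) so that
#' metric-learning recovery is identifiable; the remaining 0.4 is spread
#' uniformly over the other nine components.
#'
#' @param weights Nonnegative 12-vector summing to 1 (ordered as
#'   [similarity_components()]).
#' @param noise_sd Nonnegative standard deviation of the score noise.
#' @param seed Integer seed for the noise stream.
#' @return Object of class `oracle_config`.
#' @export
oracle_config <- function(weights = NULL, noise_sd = 0.05, seed = 1L) {
  comps <- similarity_components()
  if (is.null(weights)) {
    weights <- stats::setNames(rep(0.4 / 9, 12L), comps)
    weights[c("comorbidity", "labs", "text_set")] <- 0.2
  }
  if (length(weights) != 12L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must be 12 nonnegative values summing to 1",
         call. = FALSE)
  }
  if (is.null(names(weights))) names(weights) <- comps
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  structure(list(weights = weights, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "oracle_config")
}

#' Score pair-similarity vectors with the expert oracle
#'
#' `score = clip(sum_k w_k v_k + eps, 0, 1)` with `eps ~ N(0, noise_sd)`
#' drawn from the oracle's seeded stream; the same oracle applied to the same
#' vectors always returns the same scores.
#'
#' @param v A 12-vector, or a matrix / data frame of pair vectors (rows) with
#'   the 12 similarity components.
#' @param oracle An [oracle_config()].
#' @return Numeric score(s) in `[0, 1]`.
#' @export
expert_score_oracle <- function(v, oracle) {
  stopifnot(inherits(oracle, "oracle_config"))
  if (is.data.frame(v)) v <- as.matrix(v[similarity_components()])
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != 12L) {
    stop("pair vectors must have 12 components (got ", ncol(v), ")",
         call. = FALSE)
  }
  if (any(!is.finite(v))) stop("pair vector components must be finite",
                               call. = FALSE)
  raw <- drop(v %*% oracle$weights)
  eps <- if (oracle$noise_sd > 0) {
    with_local_seed(oracle$seed, stats::rnorm(length(raw), 0, oracle$noise_sd))
  } else 0
  pmin(1, pmax(0, raw + eps))
}

#' Expert-label the pairs of a labeled patient subset
#'
#' Selects from a pairwise similarity table the rows whose both patients
#' belong to `labeled_ids` and scores them with the oracle, emulating the
#' expert scoring all pairs among a small random patient sample.
#'
#' @param pairs Output of [pairwise_similarity_table()].
#' @param labeled_ids Character vector of patient ids shown to the expert.
#' @param oracle An [oracle_config()].
#' @return Data frame `id_a`, `id_b`, `score` (one row per labeled pair).
#' @export
expert_label_pairs <- function(pairs, labeled_ids, oracle) {
  sel <- pairs$id_a %in% labeled_ids & pairs$id_b %in% labeled_ids
  if (!any(sel)) stop("no pairs among `labeled_ids`", call. = FALSE)
  data.frame(id_a = pairs$id_a[sel], id_b = pairs$id_b[sel],
             score = expert_score_oracle(pairs[sel, , drop = FALSE], oracle))
}

#' Mask laboratory values at random
#'
#' Independently replaces each laboratory value with `NA` with probability
#' `rate`, creating the missing-data condition that [impute_missing()]
#' repairs. Seeded and reproducible.
#'
#' @param cohort An `emr_cohort`.
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with some lab values set to `NA`.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("`rate` must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  with_local_seed(seed, {
    cohort$patients <- lapply(cohort$patients, function(p) {
      mask <- stats::runif(length(p$labs)) < rate
      p$labs[mask] <- NA_real_
      p
    })
    cohort
  })
}
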