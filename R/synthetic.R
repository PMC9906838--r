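#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a large UK/Canada breast
#' cancer case series with linked expression and long follow-up: 76%
#' ER-positive, 12% HER2-positive, 53% PR-positive, 47% node-positive,
#' grade mix 9/39/48 (renormalised), median age 61.8 years, median tumour
#' size 23 mm (log-normal), 20% second-generation chemotherapy, 61%
#' hormone therapy, and follow-up with a median near 9.5 years under an
#' administrative cut-off of 29 years. Expression is z-scored with a
#' designated signature-gene block loaded on a latent tumour
#' "aggressiveness" factor (itself loading on grade, size, nodes and ER),
#' so the genomic score is confounded with the clinical covariates — the
#' structure that makes "independent prognostic value" a non-trivial
#' question. Survival follows a proportional-hazards truth
#' `h(t) = lambda * exp(PI_true + true_beta_grs * g)` with exponential
#' baseline (Weibull optional), plus other-cause mortality and uniform
#' administrative censoring.
#'
#' @param n Cohort size.
#' @param seed Integer seed; identical configs generate bit-identical
#'   cohorts.
#' @param er_pos_frac,her2_pos_frac,pr_pos_frac,node_pos_frac Marginal
#'   positive fractions.
#' @param grade_probs Probabilities of grades 1-3 (renormalised).
#' @param age_median,age_sd Age distribution (normal, truncated to
#'   22-96 years).
#' @param size_median_mm,size_sdlog Tumour size (log-normal).
#' @param chemo_second_frac,chemo_third_frac,hormone_frac,radio_frac
#'   Treatment fractions.
#' @param n_genes Number of genes in the expression matrix (includes the
#'   signature block and an `MKI67` proliferation gene).
#' @param n_signature_genes Size of the signature block (first genes).
#' @param signature_loading Loading of signature genes on the latent
#'   aggressiveness factor.
#' @param true_beta_grs True log-hazard-ratio per unit of the generated
#'   genomic score `g` (the equally weighted mean of the z-scored signature
#'   block).
#' @param baseline `"exponential"` or `"weibull"`.
#' @param baseline_rate Baseline hazard rate `lambda` (per year) for the
#'   reference patient.
#' @param weibull_shape Shape when `baseline = "weibull"`.
#' @param other_death_rate Other-cause mortality rate (per year).
#' @param censor_admin_max Administrative censoring horizon (years);
#'   censoring times are uniform on `[0, censor_admin_max]`.
#' @return An object of class `generator_config` (validated list).
#' @export
generator_config <- function(n = 1000L, seed = 1L,
                             er_pos_frac = 0.76, her2_pos_frac = 0.12,
                             pr_pos_frac = 0.53, node_pos_frac = 0.47,
                             grade_probs = c(0.09, 0.39, 0.48),
                             age_median = 61.8, age_sd = 12.5,
                             size_median_mm = 23, size_sdlog = 0.55,
                             chemo_second_frac = 0.20, chemo_third_frac = 0.01,
                             hormone_frac = 0.61, radio_frac = 0.59,
                             n_genes = 40L, n_signature_genes = 10L,
                             signature_loading = 0.8,
                             true_beta_grs = 0.5,
                             baseline = c("exponential", "weibull"),
                             baseline_rate = 0.025, weibull_shape = 1,
                             other_death_rate = 0.012,
                             censor_admin_max = 29) {
  baseline <- match.arg(baseline)
  fracs <- c(
    er_pos_frac = er_pos_frac, her2_pos_frac = her2_pos_frac,
    pr_pos_frac = pr_pos_frac, node_pos_frac = node_pos_frac,
    chemo_second_frac = chemo_second_frac, chemo_third_frac = chemo_third_frac,
    hormone_frac = hormone_frac, radio_frac = radio_frac
  )
  if (any(fracs < 0 | fracs > 1)) {
    abort(sprintf(
      "Fractions must lie in [0, 1]; offending: %s",
      paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")
    ), class = "predictgrs_config_error")
  }
  if (n < 0) abort("n must be non-negative.", class = "predictgrs_config_error")
  if (any(grade_probs < 0) || sum(grade_probs) <= 0) {
    abort("grade_probs must be non-negative and not all zero.", class = "predictgrs_config_error")
  }
  stopifnot(n_signature_genes + 6L <= n_genes || n_genes == 0L)
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed),
      er_pos_frac = er_pos_frac, her2_pos_frac = her2_pos_frac,
      pr_pos_frac = pr_pos_frac, node_pos_frac = node_pos_frac,
      grade_probs = grade_probs / sum(grade_probs),
      age_median = age_median, age_sd = age_sd,
      size_median_mm = size_median_mm, size_sdlog = size_sdlog,
      chemo_second_frac = chemo_second_frac, chemo_third_frac = chemo_third_frac,
      hormone_frac = hormone_frac, radio_frac = radio_frac,
      n_genes = as.integer(n_genes), n_signature_genes = as.integer(n_signature_genes),
      signature_loading = signature_loading, true_beta_grs = true_beta_grs,
      baseline = baseline, baseline_rate = baseline_rate,
      weibull_shape = weibull_shape, other_death_rate = other_death_rate,
      censor_admin_max = censor_admin_max
    ),
    class = "generator_config"
  )
}

# True clinical prognostic index of the generative model; stored in the
# truth record so recovery tests can supply it as the Cox offset.
true_pi <- function(clin, cfg) {
  0.02 * (clin$age - cfg$age_median) +
    0.35 * (clin$grade - 2) +
    0.45 * log(clin$size_mm / cfg$size_median_mm) +
    0.55 * log1p(clin$nodes) +
    0.25 * clin$her2 -
    0.30 * clin$er
}

#' Generate a synthetic cohort with known truth
#'
#' Draws clinical covariates, correlated z-scored expression and
#' proportional-hazards survival per the configuration, and returns the
#' cohort together with a truth record holding every latent quantity (the
#' true per-patient prognostic index, the true score `g`, the signature
#' weights and the baseline parameters) for parameter-recovery tests.
#'
#' @param config A [generator_config()].
#' @return A list: `cohort` (a [grs_cohort()], expression z-scored) and
#'   `truth` (list with `pi`, `g`, `signature`, `true_beta_grs`,
#'   `baseline_rate`, `weibull_shape`, `config`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n

  ids <- sprintf("P%05d", seq_len(n))
  age <- pmin(pmax(rnorm(n, cfg$age_median, cfg$age_sd), 22), 96)
  er <- rbinom(n, 1L, cfg$er_pos_frac)
  her2 <- rbinom(n, 1L, cfg$her2_pos_frac)
  # PR tracks ER while preserving the configured marginal
  p_pr_neg <- 0.15
  p_pr_pos <- if (cfg$er_pos_frac > 0) {
    min(max((cfg$pr_pos_frac - (1 - cfg$er_pos_frac) * p_pr_neg) / cfg$er_pos_frac, 0), 1)
  } else {
    p_pr_neg
  }
  pr <- rbinom(n, 1L, ifelse(er == 1L, p_pr_pos, p_pr_neg))
  grade <- sample.int(3L, n, replace = TRUE, prob = cfg$grade_probs)
  size_mm <- exp(rnorm(n, log(cfg$size_median_mm), cfg$size_sdlog))
  node_pos <- rbinom(n, 1L, cfg$node_pos_frac)
  nodes <- ifelse(node_pos == 1L, 1L + rpois(n, 2.5), 0L)
  detection <- sample(c("screen", "symptomatic", "unknown"), n,
    replace = TRUE, prob = c(0.35, 0.55, 0.10)
  )
  chemo <- sample(c("none", "second", "third"), n,
    replace = TRUE,
    prob = c(
      1 - cfg$chemo_second_frac - cfg$chemo_third_frac,
      cfg$chemo_second_frac, cfg$chemo_third_frac
    )
  )
  # hormone therapy concentrates in ER-positive disease, marginal preserved
  p_h_neg <- 0.07
  p_h_pos <- if (cfg$er_pos_frac > 0) {
    min(max((cfg$hormone_frac - (1 - cfg$er_pos_frac) * p_h_neg) / cfg$er_pos_frac, 0), 1)
  } else {
    p_h_neg
  }
  hormone <- rbinom(n, 1L, ifelse(er == 1L, p_h_pos, p_h_neg))
  radio <- rbinom(n, 1L, cfg$radio_frac)
  trastuzumab <- rbinom(n, 1L, ifelse(her2 == 1L, 0.3, 0))

  # latent aggressiveness ties expression to grade/size/nodes/ER
  aggressiveness <- 0.8 * (grade - 2) + 0.5 * log(size_mm / cfg$size_median_mm) +
    0.4 * node_pos - 0.5 * (er - 0.5) + rnorm(n, 0, 0.8)
  ki67_latent <- aggressiveness + rnorm(n, 0, 0.6)
  ki67 <- as.integer(ki67_latent > median(ki67_latent))

  clinical <- tibble(
    patient_id = ids, age = age, er = er, pr = pr, her2 = her2, ki67 = ki67,
    grade = as.integer(grade), size_mm = size_mm, nodes = as.integer(nodes),
    detection = detection, chemo = chemo, hormone = hormone, radio = radio,
    trastuzumab = trastuzumab,
    time_years = rep(0, n), event = rep("censored", n)
  )

  if (cfg$n_genes > 0L && n > 1L) {
    gene_ids <- c(
      sprintf("SIG%03d", seq_len(cfg$n_signature_genes)),
      "MKI67",
      sprintf("ESR%03d", 1:3),
      sprintf("RND%03d", seq_len(cfg$n_genes - cfg$n_signature_genes - 4L))
    )
    expr <- matrix(rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
      dimnames = list(gene_ids, ids)
    )
    sig_rows <- seq_len(cfg$n_signature_genes)
    expr[sig_rows, ] <- expr[sig_rows, ] +
      matrix(cfg$signature_loading * aggressiveness,
        nrow = cfg$n_signature_genes, ncol = n, byrow = TRUE
      )
    expr["MKI67", ] <- 1.4 * (ki67 - 0.5) + rnorm(n, 0, 0.45)
    for (r in sprintf("ESR%03d", 1:3)) {
      expr[r, ] <- expr[r, ] + 1.2 * (er - 0.5)
    }
    expr <- zscore_normalise(expr)
    sig_genes <- rownames(expr)[rownames(expr) %in% sprintf("SIG%03d", sig_rows)]
    g <- colMeans(expr[sig_genes, , drop = FALSE])
    signature <- signature_definition(
      name = "truth_linear",
      archetype = "linear",
      gene_weights = setNames(rep(1 / length(sig_genes), length(sig_genes)), sig_genes)
    )
  } else {
    expr <- matrix(numeric(0), nrow = 0, ncol = n, dimnames = list(NULL, ids))
    g <- setNames(rep(0, n), ids)
    signature <- NULL
  }

  pi_true <- true_pi(clinical, cfg)
  hr <- c(hormone = -0.30, chemo_second = log(0.78), chemo_third = -0.36, trastuzumab = -0.35)
  treat_lp <- ifelse(hormone == 1L, hr[["hormone"]], 0) +
    ifelse(chemo == "second", hr[["chemo_second"]],
      ifelse(chemo == "third", hr[["chemo_third"]], 0)
    ) +
    ifelse(trastuzumab == 1L, hr[["trastuzumab"]], 0)
  lp <- pi_true + cfg$true_beta_grs * g + treat_lp

  if (n > 0L) {
    u <- runif(n)
    t_bc <- if (cfg$baseline == "exponential") {
      -log(u) / (cfg$baseline_rate * exp(lp))
    } else {
      (-log(u) / (cfg$baseline_rate * exp(lp)))^(1 / cfg$weibull_shape)
    }
    t_other <- rexp(n, cfg$other_death_rate)
    t_cens <- runif(n, 0, cfg$censor_admin_max)
    time <- pmin(t_bc, t_other, t_cens)
    event <- ifelse(time == t_bc, "bc_death",
      ifelse(time == t_other, "other_death", "censored")
    )
    clinical$time_years <- time
    clinical$event <- event
  }

  cohort <- grs_cohort(clinical, expr)
  truth <- list(
    pi = setNames(pi_true, ids), g = g,
    treatment_terms = setNames(treat_lp, ids),
    treatment_log_hr = hr,
    signature = signature, true_beta_grs = cfg$true_beta_grs,
    baseline_rate = cfg$baseline_rate, weibull_shape = cfg$weibull_shape,
    config = cfg
  )
  list(cohort = cohort, truth = truth)
}

#' Simulate survival under a PREDICT-style spec
#'
#' Replaces a clinical table's follow-up with event times drawn exactly
#' from the spec's own model — `S(t | patient) = S0(t)^exp(pi + treatment
#' terms)`, inverted through the tabulated baseline — plus uniform
#' administrative censoring. Event times beyond the tabulated horizon are
#' censored there. Used for self-calibration checks: a model evaluated on
#' data simulated from itself must be calibrated.
#'
#' @param clinical Clinical table (ER stratum matching the spec).
#' @param spec A [predict_model_spec()].
#' @param seed Integer seed.
#' @param grs_term Optional per-patient extra log-hazard term.
#' @param censor_max Upper bound of the uniform censoring distribution;
#'   defaults to the baseline horizon.
#' @return The clinical tibble with `time_years` and `event` replaced.
#' @export
simulate_from_spec <- function(clinical, spec, seed = 1L, grs_term = 0,
                               censor_max = NULL) {
  set.seed(seed)
  horizon <- max(spec$baseline$time)
  censor_max <- censor_max %||% horizon
  pi_tbl <- prognostic_index(clinical, spec)
  tr <- received_treatment_terms(clinical, spec, include_chemo = TRUE)
  lp <- pi_tbl$pi + grs_term + tr
  n <- nrow(clinical)
  u <- runif(n)
  s0_target <- u^exp(-lp) # S0(T) = U^(1/exp(lp))
  t_bc <- s0_inverse(spec, s0_target)
  t_cens <- runif(n, 0, censor_max)
  time <- pmin(t_bc, t_cens, horizon)
  event <- ifelse(t_bc <= pmin(t_cens, horizon), "bc_death", "censored")
  out <- as_tibble(clinical)
  out$time_years <- time
  out$event <- event
  out
}

#' Published worked-example reclassification matrices
#'
#' Four 3x3 chemotherapy-benefit reclassification matrices (reference
#' model in rows, modified model in columns, categories
#' low/intermediate/high) transcribed from a published head-to-head
#' evaluation of genomic risk scores added to a clinical prognosis model
#' in ER-positive patients. They serve as desk-checkable fixtures for the
#' reclassification summariser: every movement statistic they imply can be
#' verified by hand.
#'
#' @param name One of `"table4a"` (Oncotype DX-like), `"table4b"`
#'   (EndoPredict-like), `"table4c"` (MammaPrint-like), `"table4d"`
#'   (Prosigna-like).
#' @return A 3x3 integer matrix.
#' @export
printed_reclassification_matrix <- function(name) {
  tables <- list(
    table4a = matrix(c(893L, 19L, 0L, 27L, 434L, 7L, 0L, 21L, 477L), 3, byrow = TRUE),
    table4b = matrix(c(890L, 22L, 0L, 46L, 407L, 15L, 0L, 49L, 449L), 3, byrow = TRUE),
    table4c = matrix(c(873L, 39L, 0L, 54L, 380L, 34L, 0L, 27L, 471L), 3, byrow = TRUE),
    table4d = matrix(c(877L, 34L, 1L, 60L, 388L, 20L, 0L, 68L, 430L), 3, byrow = TRUE)
  )
  if (!name %in% names(tables)) {
    abort(sprintf(
      "Unknown fixture `%s`; available: %s",
      name, paste(names(tables), collapse = ", ")
    ))
  }
  m <- tables[[name]]
  dimnames(m) <- list(model_a = benefit_levels, model_b = benefit_levels)
  m
}
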