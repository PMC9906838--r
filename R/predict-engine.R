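transform_fns <- list(
  identity = function(x) x,
  log = function(x) log(x),
  log1p = function(x) log1p(x),
  sqrt = function(x) sqrt(x),
  inverse = function(x) 1 / x,
  inverse_sqrt = function(x) 1 / sqrt(x),
  square = function(x) x^2
)

#' Specify a PREDICT-style absolute-risk model
#'
#' A `predict_model_spec` fully describes one ER stratum of a PREDICT-style
#' prognostic model: the covariate terms of the prognostic index (PI), the
#' treatment log-hazard-ratios, and a tabulated baseline breast-cancer-
#' specific survival curve S0(t). The PI of the reference patient (every
#' covariate at its reference value) is exactly 0, so S0 is the survival of
#' that reference patient. Separate spec instances are used for ER-positive
#' and ER-negative disease because their baseline hazards differ.
#'
#' Numeric terms contribute `coefficient * (f(x) - f(reference))` with `f`
#' one of `identity`, `log`, `log1p`, `sqrt`, `inverse`, `inverse_sqrt`,
#' `square`; categorical terms contribute a per-level coefficient with the
#' reference level at 0.
#'
#' @param er_stratum `"positive"` or `"negative"`.
#' @param terms A data frame with columns `variable`, `type`
#'   (`"numeric"`/`"categorical"`), `transform`, `reference`, `coefficient`
#'   (numeric terms) and, for categorical terms, a list-column or named list
#'   `level_coefficients`.
#' @param treatment_log_hr Named numeric vector with entries `hormone`,
#'   `chemo_second`, `chemo_third`, `trastuzumab` (log hazard ratios;
#'   negative = protective).
#' @param baseline Data frame with columns `time` (years, starting at 0)
#'   and `survival` (S0, starting at 1, non-increasing, in (0, 1]).
#' @return An object of class `predict_model_spec`.
#' @export
predict_model_spec <- function(er_stratum = c("positive", "negative"),
                               terms, treatment_log_hr, baseline) {
  er_stratum <- match.arg(er_stratum)
  terms <- as_tibble(terms)
  stopifnot(all(c("variable", "type", "coefficient") %in% names(terms)))
  baseline <- as_tibble(baseline)
  stopifnot(all(c("time", "survival") %in% names(baseline)))
  baseline <- arrange(baseline, .data$time)
  if (baseline$time[1] != 0 || baseline$survival[1] != 1) {
    abort("Baseline table must start at (time = 0, survival = 1).")
  }
  if (any(diff(baseline$survival) > 0)) abort("Baseline survival must be non-increasing.")
  if (any(baseline$survival <= 0) || any(baseline$survival > 1)) {
    abort("Baseline survival values must lie in (0, 1].")
  }
  needed <- c("hormone", "chemo_second", "chemo_third", "trastuzumab")
  missing_hr <- setdiff(needed, names(treatment_log_hr))
  if (length(missing_hr) > 0L) {
    abort(sprintf("treatment_log_hr missing: %s", paste(missing_hr, collapse = ", ")))
  }
  structure(
    list(
      er_stratum = er_stratum, terms = terms,
      treatment_log_hr = unlist(treatment_log_hr)[needed],
      baseline = baseline
    ),
    class = "predict_model_spec"
  )
}

#' @export
print.predict_model_spec <- function(x, ...) {
  cat(sprintf(
    "<predict_model_spec> ER-%s, %d covariate terms, baseline tabulated on [0, %g] years\n",
    x$er_stratum, nrow(x$terms), max(x$baseline$time)
  ))
  invisible(x)
}

#' Read a PREDICT model spec from YAML
#'
#' @param path YAML file with keys `er_stratum`, `terms`, `treatment_log_hr`
#'   and `baseline` (`time` and `survival` arrays).
#' @return A [predict_model_spec()].
#' @export
read_predict_spec <- function(path) {
  y <- yaml::read_yaml(path)
  terms <- purrr::map_dfr(y$terms, function(tm) {
    tibble(
      variable = tm$variable,
      type = tm$type %||% "numeric",
      transform = tm$transform %||% "identity",
      reference = list(tm$reference),
      coefficient = tm$coefficient %||% NA_real_,
      level_coefficients = list(tm$level_coefficients)
    )
  })
  predict_model_spec(
    er_stratum = y$er_stratum,
    terms = terms,
    treatment_log_hr = unlist(y$treatment_log_hr),
    baseline = tibble(
      time = as.numeric(y$baseline$time),
      survival = as.numeric(y$baseline$survival)
    )
  )
}

# Linear interpolation of log(-log S0) between tabulated knots; the first
# segment (S0 = 1, cloglog undefined) interpolates the cumulative hazard
# linearly from H(0) = 0 instead.
s0_at <- function(spec, t) {
  tb <- spec$baseline
  tmax <- max(tb$time)
  if (any(t < 0) || any(t > tmax)) {
    abort(sprintf("t outside the tabulated baseline range [0, %g]; no extrapolation.", tmax))
  }
  H <- -log(tb$survival)
  vapply(t, function(ti) {
    i <- findInterval(ti, tb$time)
    if (tb$time[i] == ti) {
      return(tb$survival[i])
    }
    t0 <- tb$time[i]
    t1 <- tb$time[i + 1]
    H0 <- H[i]
    H1 <- H[i + 1]
    frac <- (ti - t0) / (t1 - t0)
    if (H1 == H0) {
      return(tb$survival[i])
    }
    if (H0 == 0) { # leaving S = 1: cloglog undefined, fall back to linear hazard
      return(exp(-(H1 * frac)))
    }
    exp(-exp(log(H0) + frac * (log(H1) - log(H0))))
  }, numeric(1))
}

# Inverse of s0_at: smallest t with S0(t) <= s; Inf when s is below the
# tabulated range (event beyond the horizon).
s0_inverse <- function(spec, s) {
  tb <- spec$baseline
  H <- -log(tb$survival)
  vapply(s, function(si) {
    if (si >= 1) {
      return(0)
    }
    if (si < min(tb$survival)) {
      return(Inf)
    }
    Hs <- -log(si)
    i <- max(which(H <= Hs))
    if (H[i] == Hs) {
      return(tb$time[i])
    }
    t0 <- tb$time[i]
    t1 <- tb$time[i + 1]
    H0 <- H[i]
    H1 <- H[i + 1]
    if (H0 == 0) {
      return(t0 + (t1 - t0) * Hs / H1)
    }
    t0 + (t1 - t0) * (log(Hs) - log(H0)) / (log(H1) - log(H0))
  }, numeric(1))
}

#' Prognostic index under a PREDICT-style spec
#'
#' Computes the log-hazard-scale prognostic index PI for every patient:
#' the sum of coefficient-weighted, reference-centred covariate transforms.
#' The reference patient scores exactly 0. Optional covariates (`ki67`,
#' `detection`, `pr`) that are missing fall back to the reference level
#' with a message; missing mandatory covariates follow `na_action`.
#'
#' @param clinical Clinical data frame (see [clinical_columns()]).
#' @param spec A [predict_model_spec()].
#' @param na_action `"error"` (default) or `"reference"` for missing
#'   mandatory covariates.
#' @param check_er Verify that all patients match the spec's ER stratum.
#' @return A tibble: `patient_id`, `pi`.
#' @export
prognostic_index <- function(clinical, spec, na_action = c("error", "reference"),
                             check_er = TRUE) {
  na_action <- match.arg(na_action)
  clinical <- as_tibble(clinical)
  if (check_er && "er" %in% names(clinical) && nrow(clinical) > 0L) {
    want <- if (spec$er_stratum == "positive") 1L else 0L
    if (any(clinical$er != want, na.rm = TRUE) || any(is.na(clinical$er))) {
      abort(sprintf(
        "Clinical records do not all match the spec's ER-%s stratum.",
        spec$er_stratum
      ), class = "predictgrs_stratum_error")
    }
  }
  optional_vars <- c("ki67", "detection", "pr")
  pi <- rep(0, nrow(clinical))
  for (k in seq_len(nrow(spec$terms))) {
    tm <- spec$terms[k, ]
    v <- tm$variable
    if (!v %in% names(clinical)) abort(sprintf("Covariate `%s` not found in clinical data.", v))
    x <- clinical[[v]]
    nas <- is.na(x)
    if (any(nas)) {
      if (v %in% optional_vars || na_action == "reference") {
        inform(sprintf(
          "Covariate `%s`: %d missing value(s) set to the reference level.",
          v, sum(nas)
        ))
      } else {
        abort(sprintf("Covariate `%s` has %d missing value(s).", v, sum(nas)))
      }
    }
    if (tm$type == "categorical") {
      lev <- unlist(tm$level_coefficients[[1]])
      contrib <- rep(0, length(x))
      known <- !nas & x %in% names(lev)
      contrib[known] <- lev[x[known]]
      # reference level and NA contribute 0
      pi <- pi + contrib
    } else {
      f <- transform_fns[[tm$transform %||% "identity"]]
      if (is.null(f)) abort(sprintf("Unknown transform `%s`.", tm$transform))
      ref <- tm$reference
      if (is.list(ref)) ref <- ref[[1]]
      ref <- as.numeric(ref)
      xn <- as.numeric(x)
      xn[nas] <- ref
      pi <- pi + tm$coefficient * (f(xn) - f(ref))
    }
  }
  tibble(patient_id = clinical$patient_id, pi = pi)
}

#' Absolute survival at time t
#'
#' `S(t) = S0(t) ^ exp(pi + treatment_terms)`, with the baseline
#' interpolated on the complementary log-log scale between tabulated knots
#' (which preserves the proportional-hazards structure between knots).
#' Times beyond the tabulated range raise an error rather than
#' extrapolating.
#'
#' @param t Time in years (scalar or vector).
#' @param pi Prognostic index (scalar or vector).
#' @param treatment_terms Sum of applicable treatment log-hazard-ratios.
#' @param spec A [predict_model_spec()].
#' @return Survival probabilities in `[0, 1]`, vectorised over the longer
#'   of `t` and `pi`.
#' @export
survival_at <- function(t, pi, treatment_terms = 0, spec) {
  s0 <- s0_at(spec, t)
  s0^exp(pi + treatment_terms)
}

received_treatment_terms <- function(clinical, spec, include_chemo = TRUE) {
  hr <- spec$treatment_log_hr
  terms <- rep(0, nrow(clinical))
  terms <- terms + ifelse(!is.na(clinical$hormone) & clinical$hormone == 1L, hr[["hormone"]], 0)
  terms <- terms + ifelse(!is.na(clinical$trastuzumab) & clinical$trastuzumab == 1L, hr[["trastuzumab"]], 0)
  if (include_chemo) {
    terms <- terms + dplyr::case_when(
      clinical$chemo == "second" ~ hr[["chemo_second"]],
      clinical$chemo == "third" ~ hr[["chemo_third"]],
      TRUE ~ 0
    )
  }
  terms
}

#' Predicted survival for a cohort under received treatments
#'
#' Per-patient `S(t)` holding each patient's recorded treatments (hormone
#' therapy, trastuzumab and, when `include_chemo = TRUE`, chemotherapy)
#' fixed, with an optional already-rescaled genomic-risk-score log-hazard
#' term added to the prognostic index.
#'
#' @inheritParams prognostic_index
#' @param t Evaluation time in years (default 10).
#' @param grs_term Per-patient additional log-hazard term (scalar or vector
#'   aligned with `clinical`); supply rescaled terms from
#'   [rescale_grs_term()] so the cohort-average hazard multiplier is one.
#' @param include_chemo Include recorded chemotherapy in the treatment terms.
#' @param ... Passed to [prognostic_index()].
#' @return A tibble: `patient_id`, `pi`, `treatment_terms`, `survival`.
#' @export
predict_survival <- function(clinical, spec, t = 10, grs_term = 0,
                             include_chemo = TRUE, ...) {
  pi_tbl <- prognostic_index(clinical, spec, ...)
  tr <- received_treatment_terms(clinical, spec, include_chemo = include_chemo)
  lp <- pi_tbl$pi + grs_term
  tibble(
    patient_id = pi_tbl$patient_id,
    pi = lp,
    treatment_terms = tr,
    survival = survival_at(t, lp, tr, spec)
  )
}

#' Absolute chemotherapy benefit
#'
#' Computes 10-year (by default) breast-cancer-specific survival twice —
#' with and without the second-generation-chemotherapy log-hazard-ratio —
#' holding each patient's recorded non-chemotherapy treatments fixed, and
#' reports the difference in percentage points. An optional rescaled GRS
#' log-hazard term is added to the prognostic index in both arms.
#'
#' @inheritParams predict_survival
#' @return A tibble: `patient_id`, `pi`, `s10_no_chemo`, `s10_with_chemo`,
#'   `benefit_pct`.
#' @export
chemo_benefit <- function(clinical, spec, grs_term = 0, t = 10, ...) {
  pi_tbl <- prognostic_index(clinical, spec, ...)
  lp <- pi_tbl$pi + grs_term
  base_terms <- received_treatment_terms(clinical, spec, include_chemo = FALSE)
  s_no <- survival_at(t, lp, base_terms, spec)
  s_yes <- survival_at(t, lp, base_terms + spec$treatment_log_hr[["chemo_second"]], spec)
  tibble(
    patient_id = pi_tbl$patient_id,
    pi = lp,
    s10_no_chemo = s_no,
    s10_with_chemo = s_yes,
    benefit_pct = 100 * (s_yes - s_no)
  )
}
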