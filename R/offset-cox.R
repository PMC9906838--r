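# fitting lives outside fit_offset_cox so its `offset` argument cannot
# shadow stats::offset when the formula is evaluated
cox_offset_engine <- function(tt, ev, off, g = NULL) {
  if (is.null(g)) {
    survival::coxph(survival::Surv(tt, ev) ~ offset(off), ties = "efron")
  } else {
    survival::coxph(
      survival::Surv(tt, ev) ~ g + offset(off),
      ties = "efron",
      control = survival::coxph.control(eps = 1e-9, iter.max = 100)
    )
  }
}

event_indicator <- function(event) {
  if (is.character(event) || is.factor(event)) {
    as.integer(as.character(event) == "bc_death")
  } else {
    as.integer(event)
  }
}

#' Cox model with a fixed-coefficient prognostic-index offset
#'
#' Fits a Cox proportional hazards model for breast-cancer-specific
#' survival in which an externally derived prognostic index enters the
#' linear predictor as an offset — its coefficient constrained to one — and
#' an optional genomic risk score enters as a single free covariate. Fixing
#' the clinical index avoids re-estimating (and over-fitting) a model that
#' was validated elsewhere, and makes the fit an external validation of
#' that index; the free score coefficient measures prognostic information
#' *independent* of it. Ties are handled with the Efron approximation.
#'
#' With `score = NULL` the offset-only partial log-likelihood is returned
#' (no free parameters), which is the null model for the likelihood-ratio
#' comparison.
#'
#' @param data Data frame with one row per patient.
#' @param time,event,offset,score Bare column names: follow-up time in
#'   years, event (either a 0/1 breast-cancer-death indicator or the
#'   canonical `bc_death`/`other_death`/`censored` coding — other-cause
#'   deaths censor), the per-patient prognostic index, and (optionally) the
#'   genomic risk score.
#' @param signature Name recorded in the result.
#' @param standardise Standardise the score before fitting (the rescaling
#'   step makes the fitted term scale-consistent either way).
#' @param allow_mixed_er Mixed ER strata in `data` (detected via an `er`
#'   column) are refused unless this is set; ER-positive and ER-negative
#'   disease have different baseline hazards and are modelled separately.
#' @return An object of class `grs_fit`: list with `signature`, `beta`,
#'   `se`, `ci_95`, `hr`, `loglik`, `loglik_null`, `lr_p`, `rescale_c`,
#'   `scores`, `n`, `n_events`, and the underlying [survival::coxph()] fit.
#'   With no score, a `grs_fit` carrying only the null log-likelihood.
#' @export
fit_offset_cox <- function(data, time = time_years, event = event, offset = pi,
                           score = NULL, signature = NULL, standardise = FALSE,
                           allow_mixed_er = FALSE) {
  tt <- dplyr::pull(data, {{ time }})
  ev <- event_indicator(dplyr::pull(data, {{ event }}))
  off <- dplyr::pull(data, {{ offset }})
  if (any(!is.finite(off))) abort("Offset must be finite for every patient.")
  if (sum(ev) < 2L) abort("Need at least 2 events to fit.")
  if (!allow_mixed_er && "er" %in% names(data)) {
    if (length(unique(stats::na.omit(data$er))) > 1L) {
      abort("Mixed ER strata; fit ER-positive and ER-negative cohorts separately or set allow_mixed_er = TRUE.",
        class = "predictgrs_stratum_error"
      )
    }
  }

  score_quo <- rlang::enquo(score)
  has_score <- !rlang::quo_is_null(score_quo)

  null_fit <- cox_offset_engine(tt, ev, off)
  loglik_null <- unname(null_fit$loglik[length(null_fit$loglik)])

  if (!has_score) {
    return(new_grs_fit(
      signature = signature %||% "offset_only", beta = NA_real_, se = NA_real_,
      loglik = loglik_null, loglik_null = loglik_null, lr_p = NA_real_,
      rescale_c = NA_real_, scores = NULL, n = length(tt), n_events = sum(ev),
      fit = null_fit
    ))
  }

  g <- dplyr::pull(data, {{ score }})
  if (any(!is.finite(g))) abort("Score must be finite for every patient.")
  if (sd(g) == 0) abort("Score has no variation.", class = "predictgrs_degenerate_error")
  g_fit <- if (standardise) (g - mean(g)) / sd(g) else g

  fit <- cox_offset_engine(tt, ev, off, g_fit)
  if (!is.null(fit$info) && isTRUE(fit$info$fail)) abort("Cox fit failed to converge.")
  beta_fit <- unname(stats::coef(fit)[1])
  se_fit <- sqrt(unname(stats::vcov(fit)[1, 1]))
  # back-transform to the raw score scale when standardised
  beta <- if (standardise) beta_fit / sd(g) else beta_fit
  se <- if (standardise) se_fit / sd(g) else se_fit
  loglik <- unname(fit$loglik[length(fit$loglik)])
  lr_p <- compare_models(loglik_null, loglik, df = 1L)
  resc <- rescale_grs_term(beta, g)

  new_grs_fit(
    signature = signature %||% rlang::as_label(score_quo),
    beta = beta, se = se, loglik = loglik, loglik_null = loglik_null,
    lr_p = lr_p, rescale_c = resc$c, scores = g, n = length(tt),
    n_events = sum(ev), fit = fit
  )
}

new_grs_fit <- function(signature, beta, se, loglik, loglik_null, lr_p,
                        rescale_c, scores, n, n_events, fit) {
  structure(
    list(
      signature = signature, beta = beta, se = se,
      ci_95 = beta + c(-1, 1) * qnorm(0.975) * se,
      hr = exp(beta),
      loglik = loglik, loglik_null = loglik_null, lr_p = lr_p,
      rescale_c = rescale_c, scores = scores, n = n, n_events = n_events,
      fit = fit
    ),
    class = "grs_fit"
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  if (is.na(x$beta)) {
    cat(sprintf(
      "<grs_fit> %s: offset-only, loglik %.4f (n = %d, events = %d)\n",
      x$signature, x$loglik, x$n, x$n_events
    ))
  } else {
    cat(sprintf(
      "<grs_fit> %s: HR %.3f (95%% CI %.3f-%.3f), loglik %.4f vs null %.4f, LR p = %.3g\n",
      x$signature, x$hr, exp(x$ci_95[1]), exp(x$ci_95[2]),
      x$loglik, x$loglik_null, x$lr_p
    ))
  }
  invisible(x)
}

#' @export
tidy.grs_fit <- function(x, exponentiate = FALSE, ...) {
  if (is.na(x$beta)) {
    return(tibble(
      term = character(), estimate = numeric(), std.error = numeric(),
      conf.low = numeric(), conf.high = numeric(), p.value = numeric()
    ))
  }
  est <- c(x$beta, x$ci_95)
  if (exponentiate) est <- exp(est)
  tibble(
    term = x$signature, estimate = est[1], std.error = x$se,
    conf.low = est[2], conf.high = est[3], p.value = x$lr_p
  )
}

#' @export
glance.grs_fit <- function(x, ...) {
  tibble(
    signature = x$signature, logLik = x$loglik, logLik_null = x$loglik_null,
    lr_p = x$lr_p, rescale_c = x$rescale_c, n = x$n, n_events = x$n_events
  )
}

#' Rescale a fitted score term to a cohort-average hazard ratio of one
#'
#' When a fitted genomic-risk-score term `beta * g` is grafted onto a model
#' with a fixed baseline, the baseline stays appropriate only if the term
#' does not shift the average hazard. This computes the constant
#' `c = log(mean(exp(beta * g_i)))` so that the adjusted terms
#' `beta * g_i - c` satisfy `mean(exp(adjusted)) = 1` exactly. The
#' computation is max-shifted (log-sum-exp), so extreme `beta * g` cannot
#' overflow; the rescaling never changes the ordering of patients' hazards.
#'
#' @param beta Fitted log-hazard coefficient.
#' @param scores Per-patient score vector (finite, non-empty).
#' @return List with `c` (the rescaling constant) and `adjusted_terms`
#'   (`beta * scores - c`).
#' @export
rescale_grs_term <- function(beta, scores) {
  assert_scalar_number(beta, "beta")
  if (length(scores) == 0L || any(!is.finite(scores))) {
    abort("`scores` must be non-empty and finite.")
  }
  c_const <- log_mean_exp(beta * scores)
  list(c = c_const, adjusted_terms = beta * scores - c_const)
}

#' Likelihood-ratio comparison of nested model fits
#'
#' Refers `2 * (loglik_full - loglik_restricted)` to a chi-squared
#' distribution (analysis of deviance for nested Cox models; with the same
#' number of added parameters this ordering is equivalent to comparing AIC).
#'
#' @param loglik_restricted,loglik_full Maximised partial log-likelihoods;
#'   the full model may not be worse beyond numerical tolerance.
#' @param df Degrees of freedom (number of added parameters).
#' @return Upper-tail p-value.
#' @export
compare_models <- function(loglik_restricted, loglik_full, df = 1L) {
  assert_scalar_number(loglik_restricted, "loglik_restricted")
  assert_scalar_number(loglik_full, "loglik_full")
  stopifnot(df >= 1L)
  lr <- 2 * (loglik_full - loglik_restricted)
  if (lr < -1e-8) abort("Full model log-likelihood below restricted model: nesting violated.")
  pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}
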