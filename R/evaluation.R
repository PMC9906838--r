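#' Kaplan-Meier curve as a tidy step function
#'
#' Product-limit estimate of breast-cancer-specific survival (other-cause
#' deaths enter as censoring upstream, via the 0/1 indicator).
#'
#' @param times Follow-up times in years (non-negative).
#' @param events 0/1 event indicator, or the canonical
#'   `bc_death`/`other_death`/`censored` coding.
#' @return A tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` — one row per distinct observed time.
#' @export
km_curve <- function(times, events) {
  ev <- event_indicator(events)
  stopifnot(length(times) >= 1L, all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, ev) ~ 1)
  tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
}

#' Kaplan-Meier survival at a fixed time
#'
#' Step-function value at `t` (the value after the last jump at or before
#' `t`). Querying beyond the last observed time returns the value at the
#' last time, with a truncation warning.
#'
#' @inheritParams km_curve
#' @param t Query time in years.
#' @return Survival probability in `[0, 1]`.
#' @export
km_value_at <- function(times, events, t = 10) {
  curve <- km_curve(times, events)
  if (t > max(times)) {
    warn(sprintf(
      "t = %g is beyond the last observed time %g; returning the value there.",
      t, max(times)
    ))
    t <- max(times)
  }
  idx <- which(curve$time <= t)
  if (length(idx) == 0L) {
    return(1)
  }
  curve$survival[max(idx)]
}

#' Calibration as predicted-minus-observed survival
#'
#' The absolute difference, in percentage points, between the cohort-mean
#' predicted 10-year breast-cancer-specific survival and the observed
#' (Kaplan-Meier) value. Negative values mean the model underestimates
#' survival.
#'
#' @param predictions Per-patient predicted survival probabilities in
#'   `[0, 1]` (their mean is the model's cohort prediction).
#' @param observed_pct Observed survival as a percentage in `[0, 100]`,
#'   e.g. from `100 * km_value_at(...)`.
#' @return Calibration difference in percentage points.
#' @export
calibration <- function(predictions, observed_pct) {
  if (length(predictions) == 0L) abort("Empty prediction vector.")
  if (any(predictions < 0 | predictions > 1)) abort("Predictions must be probabilities in [0, 1].")
  assert_scalar_number(observed_pct, "observed_pct")
  if (observed_pct < 0 || observed_pct > 100) abort("`observed_pct` must be in [0, 100].")
  100 * mean(predictions) - observed_pct
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable patients, the one with the higher
#' risk score fails first. Pairs are comparable under censoring when the
#' shorter time ends in an event (Harrell's usability rule); ties in the
#' risk score count one half. The estimate and its asymptotic variance are
#' those of [survival::concordance()]; the 95% CI is Wald on the c scale,
#' clipped to `[0, 1]`.
#'
#' @inheritParams km_curve
#' @param risk Per-patient risk scores (higher = worse prognosis).
#' @return A list with `c`, `se`, `ci_95`, `n_pairs`.
#' @export
harrell_c <- function(times, events, risk) {
  ev <- event_indicator(events)
  cc <- survival::concordance(survival::Surv(times, ev) ~ risk, reverse = TRUE)
  counts <- cc$count
  usable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (usable == 0) abort("No comparable pairs.", class = "predictgrs_degenerate_error")
  se <- sqrt(cc$var)
  ci <- pmin(pmax(cc$concordance + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  list(c = unname(cc$concordance), se = unname(se), ci_95 = unname(ci), n_pairs = unname(usable))
}

#' Bootstrap optimism with out-of-bag testing
#'
#' Estimates how much a performance statistic is inflated by evaluating a
#' model on the data used to fit it. For each of `B` bootstrap resamples
#' (with replacement, size n): the model is refitted on the resample, the
#' statistic is computed on the resample (apparent performance) and on the
#' out-of-bag complement (test performance); the optimism is the mean of
#' (apparent - test). A prespecified, non-fitted score therefore has
#' optimism near zero, while an over-fitted model shows positive optimism.
#' The classic variant (test = the original data) is available via
#' `variant = "apparent"`.
#'
#' Replicates whose statistic fails on the out-of-bag set (e.g. no
#' comparable pairs) are skipped with a message; all replicates failing is
#' an error. One master `seed` drives per-replicate substreams, so results
#' are exactly reproducible.
#'
#' @param data Data frame resampled by rows.
#' @param fit_fun Function `data -> model` (any object `stat_fun`
#'   understands; for a prespecified score just return the data).
#' @param stat_fun Function `(model, data) -> scalar statistic` (e.g. a
#'   c-index).
#' @param B Number of bootstrap replicates.
#' @param seed Master seed.
#' @param variant `"oob"` (out-of-bag, default) or `"apparent"` (classic:
#'   apparent minus performance on the original data).
#' @return A list with `optimism`, `replicates` (tibble: `b`, `apparent`,
#'   `test`), `B_used`, `B_skipped`.
#' @export
bootstrap_optimism <- function(data, fit_fun, stat_fun, B = 100L, seed = 1L,
                               variant = c("oob", "apparent")) {
  variant <- match.arg(variant)
  stopifnot(B >= 1L)
  n <- nrow(data)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, B)
  rows <- purrr::map(seq_len(B), function(b) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    test_set <- if (variant == "oob") data[-unique(idx), , drop = FALSE] else data
    out <- tryCatch(
      {
        m <- fit_fun(boot)
        tibble(b = b, apparent = stat_fun(m, boot), test = stat_fun(m, test_set))
      },
      error = function(e) {
        inform(sprintf("Bootstrap replicate %d skipped: %s", b, conditionMessage(e)))
        NULL
      }
    )
    out
  })
  replicates <- bind_rows(rows)
  if (nrow(replicates) == 0L) abort("All bootstrap replicates failed.")
  list(
    optimism = mean(replicates$apparent - replicates$test),
    replicates = replicates,
    B_used = nrow(replicates),
    B_skipped = B - nrow(replicates)
  )
}

#' Assemble an evaluation report for one model
#'
#' Bundles the calibration and discrimination summaries the pipeline
#' reports per model: cohort-mean predicted 10-year survival, observed
#' Kaplan-Meier survival, their difference, and Harrell's c for the model's
#' risk ordering.
#'
#' @param model_name Label for the report row.
#' @param predictions Per-patient predicted S(10) in `[0, 1]`.
#' @param times,events Observed follow-up and event coding.
#' @param risk Risk scores used for discrimination (defaults to
#'   `1 - predictions`).
#' @param loglik Optional model log-likelihood to carry through.
#' @return One-row tibble: `model`, `predicted_mean_s10`, `observed_s10`,
#'   `calibration_diff`, `c_index`, `c_lo`, `c_hi`, `loglik`, `n`,
#'   `n_events`.
#' @export
evaluation_report <- function(model_name, predictions, times, events,
                              risk = NULL, loglik = NA_real_) {
  ev <- event_indicator(events)
  observed <- 100 * km_value_at(times, ev, 10)
  risk <- risk %||% (1 - predictions)
  cidx <- harrell_c(times, ev, risk)
  tibble(
    model = model_name,
    predicted_mean_s10 = 100 * mean(predictions),
    observed_s10 = observed,
    calibration_diff = calibration(predictions, observed),
    c_index = cidx$c, c_lo = cidx$ci_95[1], c_hi = cidx$ci_95[2],
    loglik = loglik, n = length(predictions), n_events = sum(ev)
  )
}
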