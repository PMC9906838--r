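test_that("Kaplan-Meier matches the hand product-limit", {
  # times (1,2,3), events (1,0,1): S(1) = 2/3, S(2) = 2/3, S(3) = 0
  expect_equal(km_value_at(c(1, 2, 3), c(1, 0, 1), 1), 2 / 3)
  expect_equal(km_value_at(c(1, 2, 3), c(1, 0, 1), 2), 2 / 3)
  expect_equal(km_value_at(c(1, 2, 3), c(1, 0, 1), 2.99), 2 / 3)
  expect_equal(km_value_at(c(1, 2, 3), c(1, 0, 1), 3), 0)

  # no events: flat at 1
  expect_equal(km_value_at(c(2, 5, 9), c(0, 0, 0), 8), 1)

  # duplicating every observation leaves the curve unchanged
  t1 <- c(1, 3, 4, 7)
  e1 <- c(1, 0, 1, 1)
  expect_equal(km_curve(t1, e1)$survival, km_curve(rep(t1, 2), rep(e1, 2))$survival)

  # beyond the last observed time: truncation warning, last value returned
  expect_warning(s_last <- km_value_at(c(1, 2), c(1, 0), 10), "beyond")
  expect_equal(s_last, 1 / 2)
})

test_that("Kaplan-Meier equals the brute-force product-limit on small instances", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(1:10, 1)
    times <- sample(1:6, n, replace = TRUE) # ties included on purpose
    events <- rbinom(n, 1, 0.6)
    for (t in c(0.5, 2, 4.5, 6)) {
      expect_equal(km_value_at(times, events, min(t, max(times))),
        oracle_km(times, events, min(t, max(times))),
        tolerance = 1e-12
      )
    }
  }
})

test_that("calibration is the predicted-minus-observed difference in points", {
  expect_equal(calibration(rep(0.497, 10), 58.5), -8.8, tolerance = 1e-9)
  expect_equal(calibration(rep(0.505, 10), 58.5), -8.0, tolerance = 1e-9)
  expect_equal(calibration(rep(0.585, 4), 58.5), 0, tolerance = 1e-9)
  expect_error(calibration(numeric(0), 50), "Empty")
  expect_error(calibration(c(0.5, 1.2), 50), "probabilities")
})

test_that("Harrell's c matches pair enumeration and its invariances", {
  # perfect ordering: higher risk dies earlier, no censoring
  expect_equal(harrell_c(4:1, rep(1, 4), 1:4)$c, 1)
  # 4 patients, 6 usable pairs, 5 concordant
  expect_equal(harrell_c(1:4, rep(1, 4), c(4, 3, 1, 2))$c, 5 / 6)
  # all risks tied: 1/2
  expect_equal(harrell_c(1:4, rep(1, 4), rep(7, 4))$c, 1 / 2)

  set.seed(55)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    times <- runif(n, 1, 10) # untied
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    risk <- rnorm(n)
    expect_equal(harrell_c(times, events, risk)$c,
      oracle_cindex(times, events, risk),
      tolerance = 1e-12
    )
    # invariance under strictly monotone transforms of risk
    expect_equal(
      harrell_c(times, events, exp(2 * risk) + 1)$c,
      harrell_c(times, events, risk)$c
    )
  }
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)),
    class = "predictgrs_degenerate_error"
  )
})

make_sim_surv <- function(n, seed, n_noise = 0) {
  set.seed(seed)
  d <- tibble::tibble(
    risk = rnorm(n),
    time_years = rexp(n, rate = 0.1 * exp(0.8 * rnorm(n))),
    event = rbinom(n, 1, 0.7)
  )
  if (n_noise > 0) {
    noise <- matrix(rnorm(n * n_noise), n, dimnames = list(NULL, paste0("x", seq_len(n_noise))))
    d <- dplyr::bind_cols(d, tibble::as_tibble(noise))
  }
  d
}

test_that("optimism of a prespecified score is near zero and reproducible", {
  d <- make_sim_surv(500, seed = 61)
  opt <- bootstrap_optimism(
    d,
    fit_fun = function(train) NULL, # nothing is fitted
    stat_fun = function(m, df) harrell_c(df$time_years, df$event, df$risk)$c,
    B = 100, seed = 9
  )
  expect_lt(abs(opt$optimism), 0.02)
  expect_equal(opt$B_used, 100)
  opt2 <- bootstrap_optimism(
    d,
    fit_fun = function(train) NULL,
    stat_fun = function(m, df) harrell_c(df$time_years, df$event, df$risk)$c,
    B = 100, seed = 9
  )
  expect_identical(opt$replicates, opt2$replicates)
})

test_that("an over-fitted many-covariate Cox model shows positive optimism", {
  d <- make_sim_surv(100, seed = 62, n_noise = 20)
  fml <- stats::as.formula(paste(
    "survival::Surv(time_years, event) ~",
    paste(paste0("x", 1:20), collapse = " + ")
  ))
  opt <- bootstrap_optimism(
    d,
    fit_fun = function(train) survival::coxph(fml, data = train),
    stat_fun = function(m, df) {
      harrell_c(df$time_years, df$event, predict(m, newdata = df, type = "lp"))$c
    },
    B = 50, seed = 10
  )
  expect_gt(opt$optimism, 0)
})

test_that("the classic apparent-minus-original optimism variant is available", {
  d <- make_sim_surv(200, seed = 63)
  opt <- bootstrap_optimism(
    d,
    fit_fun = function(train) NULL,
    stat_fun = function(m, df) harrell_c(df$time_years, df$event, df$risk)$c,
    B = 50, seed = 11, variant = "apparent"
  )
  expect_lt(abs(opt$optimism), 0.02)
})

test_that("evaluation reports are internally consistent", {
  set.seed(64)
  n <- 300
  pred <- runif(n, 0.4, 0.99)
  times <- rexp(n, 0.08)
  events <- rbinom(n, 1, 0.6)
  rep1 <- evaluation_report("toy", pred, times, events)
  expect_equal(rep1$calibration_diff,
    rep1$predicted_mean_s10 - rep1$observed_s10,
    tolerance = 1e-9
  )
  expect_true(rep1$c_index >= 0 && rep1$c_index <= 1)
  expect_equal(rep1$n, n)
})
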