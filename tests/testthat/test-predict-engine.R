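shipped_spec <- function(stratum = "er_positive") {
  read_predict_spec(system.file(
    file.path("extdata/configs/predict", paste0(stratum, ".yaml")),
    package = "predictgrs"
  ))
}

test_that("the reference patient has prognostic index exactly zero", {
  spec <- shipped_spec()
  ref <- toy_clinical(1, age = 60, size_mm = 20, nodes = 0L, grade = 1L,
    her2 = 0L, ki67 = 0L, detection = "symptomatic"
  )
  expect_equal(prognostic_index(ref, spec)$pi, 0)
})

test_that("prognostic index follows hand arithmetic and monotonicity", {
  spec <- toy_spec(nodes_coef = 0.3)
  expect_equal(prognostic_index(toy_clinical(1, nodes = 2L), spec)$pi, 0.6)
  pi2 <- prognostic_index(toy_clinical(1, nodes = 2L), spec)$pi
  pi3 <- prognostic_index(toy_clinical(1, nodes = 3L), spec)$pi
  expect_gt(pi3, pi2)
})

test_that("ER stratum mismatches and missing covariates are handled per rule", {
  spec <- toy_spec(er_stratum = "positive")
  expect_error(prognostic_index(toy_clinical(1, er = 0L), spec),
    class = "predictgrs_stratum_error"
  )
  # optional covariates fall back to the reference level with a message
  full <- shipped_spec()
  clin <- toy_clinical(1, ki67 = NA_integer_)
  expect_message(pi_opt <- prognostic_index(clin, full)$pi, "ki67")
  expect_equal(pi_opt, 0)
  # mandatory covariates error by default, reference with na_action
  clin2 <- toy_clinical(1, grade = NA_integer_)
  expect_error(suppressMessages(prognostic_index(clin2, full)), "grade")
  expect_message(
    pi_ref <- prognostic_index(clin2, full, na_action = "reference")$pi,
    "grade"
  )
  expect_equal(pi_ref, 0)
})

test_that("survival_at matches S0(t)^exp(pi + terms) hand values", {
  spec <- toy_spec(s0_10 = 0.9)
  expect_equal(survival_at(10, pi = log(2), spec = spec), 0.81)
  expect_equal(survival_at(10, pi = 0, spec = spec), 0.9)
  expect_equal(
    survival_at(10, pi = log(2), treatment_terms = log(0.75), spec = spec),
    0.9^1.5
  )
  expect_error(survival_at(16, pi = 0, spec = spec), "no extrapolation")
})

test_that("baseline interpolation is cloglog-linear between knots and invertible", {
  # knots sampled from a known smooth hazard H(t) = 0.01 t^2, so the
  # interpolated value can be computed independently from the same formula
  times <- 0:15
  H <- 0.01 * times^2
  spec <- predict_model_spec(
    er_stratum = "positive",
    terms = tibble::tibble(
      variable = "nodes", type = "numeric",
      transform = "identity", reference = 0, coefficient = 0
    ),
    treatment_log_hr = c(hormone = 0, chemo_second = 0, chemo_third = 0, trastuzumab = 0),
    baseline = tibble::tibble(time = times, survival = exp(-H))
  )
  # at the knots: exact table values
  expect_equal(survival_at(times, pi = 0, spec = spec), exp(-H))
  # between knots (t in [2, 3]): log H interpolates linearly
  t_mid <- 2.4
  logH_mid <- log(H[3]) + (t_mid - 2) / 1 * (log(H[4]) - log(H[3]))
  expect_equal(survival_at(t_mid, pi = 0, spec = spec), exp(-exp(logH_mid)))
  # inverse round-trip across the curve
  for (s in c(0.999, 0.97, 0.9, 0.85, exp(-H[16]) + 1e-6)) {
    t_inv <- predictgrs:::s0_inverse(spec, s)
    expect_equal(predictgrs:::s0_at(spec, t_inv), s, tolerance = 1e-10)
  }
  # monotone non-increasing in t and in pi
  grid <- seq(0, 15, by = 0.37)
  surv <- survival_at(grid, pi = 0.3, spec = spec)
  expect_true(all(diff(surv) <= 1e-12))
  expect_true(all(
    survival_at(10, pi = c(0, 0.5, 1, 2), spec = spec) ==
      cummin(survival_at(10, pi = c(0, 0.5, 1, 2), spec = spec))
  ))
})

test_that("chemotherapy benefit reproduces the worked example and null effect", {
  # pi = ln 2 via one node with coefficient ln 2; S0(10) = 0.9; chemo HR 0.75
  spec <- toy_spec(s0_10 = 0.9, nodes_coef = log(2), chemo_lhr = log(0.75))
  clin <- toy_clinical(1, nodes = 1L)
  ben <- chemo_benefit(clin, spec)
  expect_equal(ben$s10_no_chemo, 0.81)
  expect_equal(ben$s10_with_chemo, 0.9^1.5)
  expect_equal(ben$benefit_pct, 100 * (0.9^1.5 - 0.81)) # ~ 4.38 points
  expect_equal(ben$benefit_pct, 100 * (ben$s10_with_chemo - ben$s10_no_chemo),
    tolerance = 1e-12
  )

  null_spec <- toy_spec(chemo_lhr = 0)
  ben0 <- chemo_benefit(toy_clinical(5, nodes = c(0L, 1L, 3L, 6L, 10L)), null_spec)
  expect_equal(ben0$benefit_pct, rep(0, 5))
})

test_that("benefit is positive for protective chemotherapy and probabilities valid", {
  spec <- toy_spec(s0_10 = 0.85, chemo_lhr = log(0.7))
  clin <- toy_clinical(20, nodes = as.integer(0:19))
  ben <- chemo_benefit(clin, spec)
  expect_true(all(ben$benefit_pct > 0))
  expect_true(all(ben$s10_no_chemo >= 0 & ben$s10_no_chemo <= 1))
  expect_true(all(ben$s10_with_chemo >= 0 & ben$s10_with_chemo <= 1))
})

test_that("predict_survival holds received treatments fixed and accepts a GRS term", {
  spec <- toy_spec(s0_10 = 0.9, chemo_lhr = log(0.75))
  clin <- toy_clinical(2, nodes = c(0L, 0L), chemo = c("none", "second"))
  pred <- predict_survival(clin, spec)
  expect_equal(pred$survival, c(0.9, 0.9^0.75))
  # a rescaled GRS term with mean HR 1 leaves the mean hazard multiplier at 1
  g <- c(-1, 1)
  adj <- rescale_grs_term(0.4, g)$adjusted_terms
  expect_equal(mean(exp(adj)), 1, tolerance = 1e-12)
  pred_grs <- predict_survival(clin, spec, grs_term = adj)
  expect_equal(pred_grs$survival, c(0.9^exp(adj[1]), (0.9^0.75)^exp(adj[2])))
})
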