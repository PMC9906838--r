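# Programmatic fixtures shared across test files.

toy_clinical <- function(n = 1, ...) {
  base <- tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = 60, er = 1L, pr = 1L, her2 = 0L, ki67 = 0L, grade = 1L,
    size_mm = 20, nodes = 0L, detection = "symptomatic", chemo = "none",
    hormone = 0L, radio = 0L, trastuzumab = 0L,
    time_years = 5, event = "censored"
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# Single numeric-term spec with a baseline knot exactly at t = 10, so the
# hand-computable examples hit a tabulated value, not an interpolation.
toy_spec <- function(s0_10 = 0.9, er_stratum = "positive",
                     nodes_coef = 0.3, chemo_lhr = log(0.75)) {
  predict_model_spec(
    er_stratum = er_stratum,
    terms = tibble::tibble(
      variable = "nodes", type = "numeric", transform = "identity",
      reference = 0, coefficient = nodes_coef
    ),
    treatment_log_hr = c(
      hormone = 0, chemo_second = chemo_lhr,
      chemo_third = 0, trastuzumab = 0
    ),
    baseline = tibble::tibble(
      time = c(0, 5, 10, 15),
      survival = c(1, sqrt(s0_10), s0_10, s0_10 * 0.95)
    )
  )
}

toy_expression <- function(genes, values_by_patient) {
  # values_by_patient: named list patient -> numeric vector over genes
  mat <- do.call(cbind, values_by_patient)
  rownames(mat) <- genes
  mat
}

# Small untied survival data set for Cox oracle checks.
random_survival_toy <- function(n, seed) {
  set.seed(seed)
  list(
    time = round(sort(runif(n, 1, 20)) + seq_len(n) * 1e-3, 6), # untied
    status = rbinom(n, 1, 0.7),
    lp = rnorm(n)
  )
}
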