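# Numerically safe log(mean(exp(x))) via max-shift.
log_mean_exp <- function(x) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  m <- max(x)
  m + log(mean(exp(x - m)))
}

# Round half away from zero to `digits` (base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shared check that a genes x samples matrix is row-wise z-scored.
is_zscored <- function(mat, tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) == 0L) {
    return(TRUE)
  }
  mu <- apply(mat, 1L, function(v) mean(v[is.finite(v)]))
  sg <- apply(mat, 1L, function(v) sd(v[is.finite(v)]))
  all(abs(mu) < tol) && all(abs(sg - 1) < tol)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
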