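#' Dichotomise a marker by a two-component Gaussian mixture
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximisation and calls each observation positive when its
#' posterior probability of belonging to the higher-mean component exceeds
#' 0.5 (a posterior of exactly 0.5 is assigned negative — a deterministic,
#' conservative tie rule). The intended use is surrogate KI67 status from
#' MKI67 expression, where immunohistochemistry is unavailable but the
#' z-scored expression of the proliferation marker is bimodal.
#'
#' Initialisation is deterministic: the data are split at the median and
#' each half seeds one component, so repeated runs are identical. Positivity
#' is tied to the larger fitted mean, never to component order, so the
#' labelling is stable under component relabelling.
#'
#' @param values Numeric vector (optionally named by patient id) of one
#'   gene's expression; at least 10 finite values with non-zero spread.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations; non-convergence yields a warning
#'   and the best iterate, flagged in the result.
#' @return An object of class `grs_mixture`: list with `assignments`
#'   (tibble: `id`, `value`, `posterior_positive`, `status`), `parameters`
#'   (tibble: `component`, `mean`, `sd`, `weight`), `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`.
#' @export
surrogate_status_mixture <- function(values, tol = 1e-8, max_iter = 500L) {
  ids <- names(values) %||% as.character(seq_along(values))
  keep <- is.finite(values)
  v <- as.numeric(values[keep])
  if (length(v) < 10L) abort("Need at least 10 finite values to fit the mixture.")
  if (sd(v) == 0) abort("All values identical; mixture is undefined.")

  # deterministic median-split initialisation
  med <- median(v)
  lo <- v[v <= med]
  hi <- v[v > med]
  if (length(hi) < 2L) { # heavy ties at the median
    lo <- v[v < med]
    hi <- v[v >= med]
  }
  sd_floor <- 1e-6 * sd(v)
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(sd(lo), sd(hi)), sd_floor)
  pi1 <- length(lo) / length(v)

  loglik_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * dnorm(v, mu[1], sg[1])
    d2 <- (1 - pi1) * dnorm(v, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    loglik_trace <- c(loglik_trace, ll)
    if (it > 1L && abs(ll - loglik_trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    r1 <- d1 / tot
    pi1 <- mean(r1)
    mu[1] <- sum(r1 * v) / sum(r1)
    mu[2] <- sum((1 - r1) * v) / sum(1 - r1)
    sg[1] <- max(sqrt(sum(r1 * (v - mu[1])^2) / sum(r1)), sd_floor)
    sg[2] <- max(sqrt(sum((1 - r1) * (v - mu[2])^2) / sum(1 - r1)), sd_floor)
  }
  if (!converged) {
    warn(sprintf("Mixture EM did not converge in %d iterations; returning best iterate.", max_iter))
  }

  # positivity follows the larger mean, not the component index
  high <- which.max(mu)
  w_high <- if (high == 1L) pi1 else 1 - pi1
  d_high <- w_high * dnorm(v, mu[high], sg[high])
  d_low <- (1 - w_high) * dnorm(v, mu[-high], sg[-high])
  post <- d_high / pmax(d_high + d_low, .Machine$double.xmin)
  status <- post > 0.5 # exactly 0.5 -> negative

  assignments <- tibble(
    id = ids[keep], value = v,
    posterior_positive = post, status = as.integer(status)
  )
  parameters <- tibble(
    component = c("low", "high"),
    mean = c(mu[-high], mu[high]),
    sd = c(sg[-high], sg[high]),
    weight = c(1 - w_high, w_high)
  )
  structure(
    list(
      assignments = assignments, parameters = parameters,
      loglik = loglik_trace[length(loglik_trace)],
      loglik_trace = loglik_trace, converged = converged,
      n_iter = length(loglik_trace)
    ),
    class = "grs_mixture"
  )
}

#' @export
print.grs_mixture <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<grs_mixture> means %.3f / %.3f, weights %.2f / %.2f, %d positive of %d (loglik %.3f, %s)\n",
    p$mean[1], p$mean[2], p$weight[1], p$weight[2],
    sum(x$assignments$status), nrow(x$assignments), x$loglik,
    if (x$converged) sprintf("converged in %d iterations", x$n_iter) else "not converged"
  ))
  invisible(x)
}

#' @export
tidy.grs_mixture <- function(x, ...) x$parameters

#' @export
glance.grs_mixture <- function(x, ...) {
  tibble(
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n = nrow(x$assignments), n_positive = sum(x$assignments$status)
  )
}

#' @export
autoplot.grs_mixture <- function(object, bins = 40, ...) {
  p <- object$parameters
  grid <- seq(min(object$assignments$value), max(object$assignments$value), length.out = 200)
  dens <- bind_rows(
    tibble(value = grid, density = p$weight[1] * dnorm(grid, p$mean[1], p$sd[1]), component = "low"),
    tibble(value = grid, density = p$weight[2] * dnorm(grid, p$mean[2], p$sd[2]), component = "high")
  )
  ggplot2::ggplot(object$assignments, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component)
    ) +
    ggplot2::labs(
      x = "expression", y = "density",
      title = "Two-component mixture dichotomisation"
    )
}
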