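# Independent brute-force oracles: direct transcriptions of the defining
# formulas, kept deliberately naive (loops, no shared code with R/).

# Cox partial log-likelihood by explicit risk-set summation (valid for
# untied event times, where Breslow and Efron coincide).
oracle_cox_loglik <- function(time, status, lp) {
  ll <- 0
  for (i in which(status == 1)) {
    risk_set <- which(time >= time[i])
    ll <- ll + lp[i] - log(sum(exp(lp[risk_set])))
  }
  ll
}

# Product-limit estimate at time t by explicit multiplication.
oracle_km <- function(times, events, t) {
  s <- 1
  for (u in sort(unique(times[events == 1 & times <= t]))) {
    d <- sum(times == u & events == 1)
    n_risk <- sum(times >= u)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Harrell's c by pair enumeration: a pair is usable when the shorter time
# ends in an event; risk ties count one half. Tied times are skipped, so
# use untied fixtures.
oracle_cindex <- function(times, events, risk) {
  num <- den <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (times[i] == times[j]) next
      shorter <- if (times[i] < times[j]) i else j
      longer <- if (shorter == i) j else i
      if (events[shorter] != 1) next
      den <- den + 1
      if (risk[shorter] > risk[longer]) {
        num <- num + 1
      } else if (risk[shorter] == risk[longer]) num <- num + 0.5
    }
  }
  num / den
}
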