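# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (forward recursions, term-by-term
# products, closed forms) rather than calling the code paths they check.

# forward-solve the per-interval balance equations for whole reporting
# intervals: given D, C per interval and the starting state, reproduce the
# survival probabilities and numbers at risk at interval ends
forward_level1 <- function(D, C, S0 = 1, R0) {
  S <- numeric(length(D) + 1); R <- numeric(length(D) + 1)
  S[1] <- S0; R[1] <- R0
  for (k in seq_along(D)) {
    denom <- R[k] - C[k] / 2
    S[k + 1] <- S[k] * (denom - D[k]) / denom
    R[k + 1] <- R[k] - C[k] - D[k]
  }
  list(S = S, R = R)
}

# forward-solve the half-interval system: D1, D2 are the two half-interval
# event counts and C the reporting-interval censorship total
forward_level2 <- function(D1, D2, C, S0 = 1, R0) {
  m <- length(D1)
  S_half <- numeric(m); S_end <- numeric(m + 1); R <- numeric(m + 1)
  S_end[1] <- S0; R[1] <- R0
  for (k in seq_len(m)) {
    S_half[k] <- S_end[k] * (R[k] - C[k] / 4 - D1[k]) / (R[k] - C[k] / 4)
    S_end[k + 1] <- S_half[k] *
      (R[k] - 3 * C[k] / 4 - D1[k] - D2[k]) / (R[k] - 3 * C[k] / 4 - D1[k])
    R[k + 1] <- R[k] - D1[k] - D2[k] - C[k]
  }
  list(S_half = S_half, S_end = S_end, R = R)
}

# a random internally consistent (S, R) table: simulate a small cohort with
# events and censorings, then read off true survival fractions and counts
random_sr_table <- function(m = 5, n0 = 200) {
  S <- c(1, cumprod(stats::runif(m, 0.6, 0.99)))
  # at-risk counts drop at least as fast as survival (extra loss = censoring)
  keep <- S[-1] / S[-(m + 1)] * stats::runif(m, 0.75, 1)
  R <- n0 * c(1, cumprod(keep))
  list(S = S, R = R)
}

# term-by-term product likelihood (naive evaluation of the three-term form)
naive_loglik <- function(counts, par, family = "weibull") {
  fam <- kmrecon::surv_family(family)
  S <- function(t) fam$surv(t, par)
  t_max <- max(counts$end)
  total <- S(t_max)^attr(counts, "residual_at_risk")
  for (k in seq_len(nrow(counts))) {
    a <- counts$start[k]; b <- counts$end[k]
    if (counts$events[k] > 0)
      total <- total * (S(a) - S(b))^counts$events[k]
    if (counts$censorships[k] > 0)
      total <- total * S((a + b) / 2)^counts$censorships[k]
  }
  log(total)
}

# km_summary built from an exact parametric curve: survival read off the
# true survivor function and at-risk counts proportional to it (the
# no-censoring idealisation)
exact_curve_summary <- function(lambda, gamma, n0 = 1000,
                                risk_times = seq(0, 10, 2)) {
  grid <- kmrecon:::quarter_grid(risk_times)
  S <- exp(-lambda * grid^gamma)
  R <- n0 * exp(-lambda * risk_times^gamma)
  kmrecon::km_summary(risk_times, R, grid, S)
}

# a stub fitted model with prescribed covariance, for sampling tests
stub_fit <- function(par, vcov, family = "weibull") {
  L <- tryCatch(t(chol(vcov)), error = function(e) {
    e <- eigen(vcov, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
  })
  structure(list(family = family, par = par, loglik = NA_real_,
                 AIC = NA_real_, npar = length(par), vcov = vcov, chol = L,
                 mean_survival = kmrecon::mean_survival(par, family)),
            class = "km_fit")
}
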