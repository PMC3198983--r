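test_that("interval-censored log-likelihood matches the naive product", {
  set.seed(314)
  for (i in 1:20) {
    cnt <- interval_counts(
      start = c(0, 1, 2), end = c(1, 2, 3),
      events = sample(0:5, 3, replace = TRUE),
      censorships = sample(0:3, 3, replace = TRUE),
      n_at_risk_start = c(20, 14, 9), residual_at_risk = sample(0:4, 1),
      report_interval = 1:3)
    for (fam in c("weibull", "lognormal")) {
      par <- switch(fam, weibull = c(runif(1, .05, .5), runif(1, .5, 2)),
                    lognormal = c(runif(1, 0, 1.5), runif(1, .3, 1.5)))
      expect_equal(interval_censored_loglik(cnt, par, fam),
                   naive_loglik(cnt, par, fam), tolerance = 1e-10)
    }
  }
})

test_that("empty data gives zero log-likelihood", {
  cnt <- interval_counts(0, 1, 0, 0, 0, residual_at_risk = 0)
  expect_identical(interval_censored_loglik(cnt, c(0.5, 1)), 0)
})

test_that("single-interval exponential likelihood maximises at 4 log 2", {
  # one event in [0, 1/4), one patient still at risk at 1/4:
  # log L = log(1 - exp(-lambda/4)) - lambda/4, maximised at lambda = 4 ln 2
  cnt <- interval_counts(0, 0.25, events = 1, censorships = 0,
                         n_at_risk_start = 2, residual_at_risk = 1)
  lam <- seq(0.5, 6, by = 0.25)
  ll <- vapply(lam, function(l) interval_censored_loglik(cnt, l, "exponential"),
               numeric(1))
  expect_equal(ll, log(1 - exp(-lam / 4)) - lam / 4, tolerance = 1e-12)
  fit <- fit_mle(cnt, "exponential")
  expect_equal(unname(fit$par), 4 * log(2), tolerance = 1e-6)
})

test_that("MLE recovers the generating curve from an exact summary", {
  summ <- exact_curve_summary(0.1, 1, n0 = 10000)
  fit <- fit_mle(reconstruct_ipd(summ), "weibull")
  expect_equal(unname(fit$par), c(0.1, 1), tolerance = 0.02)
  expect_equal(fit$mean_survival, 10, tolerance = 0.02)
})

test_that("MLE beats a parameter grid search and the generating truth", {
  spec <- trial_spec(150, lambda = 0.2, gamma = 0.8, extra_cens_mean = NULL)
  cnt <- reconstruct_ipd(summarize_trial(simulate_trial(spec, seed = 8), spec))
  fit <- fit_mle(cnt, "weibull")
  grid <- expand.grid(l = exp(seq(log(0.02), log(2), length.out = 80)),
                      g = exp(seq(log(0.2), log(3), length.out = 80)))
  grid_ll <- mapply(function(l, g)
    interval_censored_loglik(cnt, c(l, g), "weibull"), grid$l, grid$g)
  expect_gte(fit$loglik, max(grid_ll))
  expect_gte(fit$loglik, interval_censored_loglik(cnt, c(0.2, 0.8), "weibull"))
})

test_that("interval fit agrees with survreg on integer pseudo-data", {
  spec <- trial_spec(120, lambda = 0.15, gamma = 1.2, extra_cens_mean = 5)
  ipd <- simulate_trial(spec, seed = 21)
  qgrid <- seq(0, 10, 0.5)
  br <- cut(ipd$time, qgrid, right = FALSE)
  ev <- tapply(ipd$event, br, sum); ev[is.na(ev)] <- 0
  cn <- tapply(1 - ipd$event, br, sum); cn[is.na(cn)] <- 0
  n0 <- nrow(ipd) - cumsum(c(0, (ev + cn)[-20]))
  cnt <- interval_counts(qgrid[-21], qgrid[-1], ev, cn, n0,
                         residual_at_risk = sum(ipd$time > 10))
  fit <- fit_mle(cnt, "weibull")
  a <- qgrid[-21]; b <- qgrid[-1]; m <- (a + b) / 2
  t1 <- c(rep(a, ev), rep(m, cn)); t1[t1 == 0] <- 1e-9
  t2 <- c(rep(b, ev), rep(NA, sum(cn)))
  sr <- survival::survreg(survival::Surv(t1, t2, type = "interval2") ~ 1,
                          dist = "weibull")
  expect_equal(unname(fit$par),
               unname(c(exp(-coef(sr) / sr$scale), 1 / sr$scale)),
               tolerance = 1e-3)
})

test_that("fixing the Weibull shape at one reproduces the exponential fit", {
  spec <- trial_spec(200, lambda = 0.1, gamma = 1)
  cnt <- reconstruct_ipd(summarize_trial(simulate_trial(spec, seed = 3), spec))
  fit_exp <- fit_mle(cnt, "exponential")
  prof <- optimize(function(l)
    -interval_censored_loglik(cnt, c(l, 1), "weibull"), c(1e-4, 2),
    tol = 1e-10)
  expect_equal(unname(fit_exp$par), prof$minimum, tolerance = 1e-5)
  expect_equal(fit_exp$loglik, -prof$objective, tolerance = 1e-8)
})

test_that("model selection minimises the information criterion", {
  spec <- trial_spec(300, lambda = 0.1, gamma = 1)
  cnt <- reconstruct_ipd(summarize_trial(simulate_trial(spec, seed = 12), spec))
  fits <- lapply(c("weibull", "exponential"), function(f) fit_mle(cnt, f))
  expect_identical(select_best(fits[[1]])$family, "weibull")
  # exponential data: the one-parameter fit wins on the AIC penalty
  expect_lte(fits[[1]]$loglik - fits[[2]]$loglik, 1)  # nesting, near-equal
  expect_identical(select_best(fits)$family, "exponential")
  # plain arithmetic: lower criterion wins
  f1 <- fits[[1]]; f2 <- fits[[2]]
  f1$loglik <- -50; f1$AIC <- 104; f2$loglik <- -48.5; f2$AIC <- 99
  expect_identical(select_best(list(f1, f2), alpha = 2)$loglik, -48.5)
})

test_that("parameter sampling reproduces the fitted mean and covariance", {
  # degenerate covariance: every draw is the estimate itself
  fit0 <- stub_fit(c(lambda = 0.2, gamma = 1.1), matrix(0, 2, 2))
  d0 <- sample_parameters(fit0, 50, seed = 1)
  expect_true(all(d0[, 1] == 0.2) && all(d0[, 2] == 1.1))
  expect_identical(se_of_mean(fit0, 100, seed = 1), 0)
  # law of large numbers against the prescribed moments
  V <- matrix(c(4e-4, 1e-4, 1e-4, 9e-4), 2)
  fit <- stub_fit(c(lambda = 0.3, gamma = 1), V)
  dr <- sample_parameters(fit, 1e5, seed = 42)
  se_mean <- sqrt(diag(V) / 1e5)
  expect_true(all(abs(colMeans(dr) - fit$par) < 3 * se_mean))
  expect_equal(stats::cov(dr), V, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("simulated standard error of the mean matches the delta method", {
  # exponential: mean = 1/lambda, so SE(mean) ~ sd(lambda)/lambda^2
  V <- matrix(1e-6, 1, 1)
  fit <- stub_fit(c(lambda = 0.2), V, family = "exponential")
  se <- se_of_mean(fit, n_draws = 2e5, seed = 9)
  expect_equal(se, sqrt(1e-6) / 0.2^2, tolerance = 0.05)
  # seed-stability at large draw counts
  se2 <- se_of_mean(fit, n_draws = 1e5, seed = 101)
  se3 <- se_of_mean(fit, n_draws = 1e5, seed = 202)
  expect_equal(se2, se3, tolerance = 0.01)
})

test_that("two-arm shared-shape fit recovers the hazard ratio", {
  # identical arms: hazard ratio is exactly one
  summ <- exact_curve_summary(0.15, 1, n0 = 800)
  cnt <- reconstruct_ipd(summ)
  same <- fit_two_group(cnt, cnt)
  expect_equal(same$hazard_ratio, 1, tolerance = 1e-6)
  # arms built with a true ratio of 0.5 under a shared shape
  cnt_b <- reconstruct_ipd(exact_curve_summary(0.075, 1, n0 = 800))
  two <- fit_two_group(cnt, cnt_b)
  expect_equal(two$hazard_ratio, 0.5, tolerance = 0.05 * 0.5)
  # nesting: the constrained joint fit cannot beat separate maximisations
  sep <- fit_mle(cnt, "weibull")$loglik + fit_mle(cnt_b, "weibull")$loglik
  expect_lte(two$loglik, sep + 1e-6)
})

test_that("degenerate inputs raise errors rather than silent misfits", {
  no_events <- interval_counts(0, 1, 0, 5, 10, residual_at_risk = 5)
  expect_error(fit_mle(no_events), "no events")
  fit <- stub_fit(c(0.1, 1), matrix(0, 2, 2))
  fit$vcov <- NULL; fit$chol <- NULL
  expect_error(sample_parameters(fit, 10), "covariance")
})
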