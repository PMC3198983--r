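test_that("whole-interval reconstruction solves the balance equations", {
  # no censoring: at-risk drop exactly tracks survival
  c1 <- reconstruct_level1(c(1, 0.5), c(100, 50))
  expect_equal(c1$events, 50)
  expect_equal(c1$censorships, 0)
  # flat survival: the whole drop in at-risk numbers is censoring
  c2 <- reconstruct_level1(c(1, 1), c(100, 80))
  expect_equal(c2$events, 0)
  expect_equal(c2$censorships, 20)
  # general case, checked by forward-solving the balance equations
  c3 <- reconstruct_level1(c(1, 0.8, 0.6), c(100, 70, 40))
  expect_equal(c3$events, c(170 * 0.2 / 1.8, 110 * 0.2 / 1.4),
               tolerance = 1e-12)
  expect_equal(c3$censorships, c(2 * 10 / 1.8, 2 * 10 / 1.4),
               tolerance = 1e-12)
  fw <- forward_level1(c3$events, c3$censorships, S0 = 1, R0 = 100)
  expect_equal(fw$S, c(1, 0.8, 0.6), tolerance = 1e-9)
  expect_equal(fw$R, c(100, 70, 40), tolerance = 1e-9)
})

test_that("half-interval reconstruction recovers a forward-built instance", {
  # built by forward-solving with D1 = D2 = 10, C = 20 from (S0=1, R0=100)
  cnt <- reconstruct_level2(c(1, 0.894737, 0.775439), c(100, 60),
                            times = c(0, 1))
  expect_equal(cnt$events, c(10, 10), tolerance = 1e-3)
  expect_equal(cnt$censorships, c(10, 10), tolerance = 1e-3)
  # reconstructed midpoint at-risk count R(t+1/2) = R - D1 - C/2
  expect_equal(cnt$n_at_risk_start[2], 80, tolerance = 1e-3)
})

test_that("round-trip: forward-solving reconstructed counts reproduces S and R", {
  set.seed(421)
  for (i in 1:200) {
    tab <- random_sr_table(m = sample(3:7, 1))
    l1 <- reconstruct_level1(tab$S, tab$R)
    fw <- forward_level1(l1$events, l1$censorships, tab$S[1], tab$R[1])
    expect_equal(fw$S, tab$S, tolerance = 1e-9)
    expect_equal(fw$R, tab$R, tolerance = 1e-9)
  }
  # half-interval system: random S at half points between the risk times
  for (i in 1:200) {
    m <- sample(2:5, 1)
    tab <- random_sr_table(m = m)
    S_half <- sqrt(tab$S[-(m + 1)] * tab$S[-1]) *
      stats::runif(m, 0.985, 1.015)
    S_half <- pmin(S_half, tab$S[-(m + 1)])
    S_half <- pmax(S_half, tab$S[-1])
    S2 <- numeric(2 * m + 1)
    S2[seq(1, 2 * m + 1, 2)] <- tab$S
    S2[seq(2, 2 * m, 2)] <- S_half
    l2 <- reconstruct_level2(S2, tab$R)
    D1 <- l2$events[seq(1, 2 * m, 2)]; D2 <- l2$events[seq(2, 2 * m, 2)]
    C <- 2 * l2$censorships[seq(1, 2 * m, 2)]
    fw <- forward_level2(D1, D2, C, tab$S[1], tab$R[1])
    expect_equal(fw$S_half, S_half, tolerance = 1e-9)
    expect_equal(fw$S_end, tab$S, tolerance = 1e-9)
    expect_equal(fw$R, tab$R, tolerance = 1e-9)
  }
})

test_that("no-censoring identity: R tracking S implies zero censorship", {
  set.seed(77)
  for (i in 1:50) {
    m <- 5
    S <- c(1, cumprod(runif(m, 0.7, 0.98)))
    R <- 400 * S  # R(t+1) = R(t) S(t+1)/S(t)
    l1 <- reconstruct_level1(S, R)
    expect_equal(l1$censorships, rep(0, m), tolerance = 1e-9)
    expect_equal(l1$events, -diff(R), tolerance = 1e-9)
  }
})

test_that("quarter-interval reconstruction conserves patients and refines totals", {
  summ <- exact_curve_summary(0.321, 0.6, n0 = 500)
  cnt <- reconstruct_level3(summ)
  expect_equal(nrow(cnt), 20L)
  # exact no-censoring curve: all loss is events, quarters sum to the drop
  expect_equal(cnt$censorships, rep(0, 20), tolerance = 1e-7)
  per_int <- tapply(cnt$events, cnt$report_interval, sum)
  expect_equal(as.vector(per_int), -diff(summ$n_at_risk), tolerance = 1e-7)
  # conservation invariant and totals
  drop <- cnt$events + cnt$censorships
  expect_equal(cnt$n_at_risk_start[-1],
               (cnt$n_at_risk_start - drop)[-20], tolerance = 1e-9)
  expect_equal(sum(drop) + attr(cnt, "residual_at_risk"),
               summ$n_at_risk[1], tolerance = 1e-9)
})

test_that("level-3 endpoint counts agree with reported at-risk numbers", {
  # even though quarter events need not sum to the level-1 D, the at-risk
  # bookkeeping must hit the reported R at every reporting time
  spec <- trial_spec(300, lambda = 0.321, gamma = 0.6)
  ipd <- simulate_trial(spec, seed = 11)
  summ <- summarize_trial(ipd, spec)
  cnt <- reconstruct_level3(summ)
  running <- summ$n_at_risk[1] - cumsum(cnt$events + cnt$censorships)
  expect_equal(running[seq(4, 20, 4)], summ$n_at_risk[-1], tolerance = 1e-9)
})

test_that("cleaning clips negatives and preserves conservation", {
  raw <- interval_counts(c(0, 0.5), c(0.5, 1), events = c(-0.2, 5),
                         censorships = c(1.2, 1), n_at_risk_start = c(10, 9),
                         residual_at_risk = 3, report_interval = c(1L, 1L))
  cl <- clean_counts(raw)
  expect_equal(cl$events, c(0, 5))
  expect_equal(cl$censorships, c(1, 1))
  expect_equal(sum(cl$events) + sum(cl$censorships),
               sum(raw$events) + sum(raw$censorships))
  # untouched when all counts are non-negative
  ok <- interval_counts(0:1, 1:2, c(2, 3), c(1, 0), c(10, 7),
                        residual_at_risk = 4, report_interval = c(1L, 2L))
  expect_equal(clean_counts(ok)$events, ok$events)
  expect_equal(attr(clean_counts(ok), "cleaning")$n_adjusted, 0L)
  # errors when the adjustment is too large to be credible
  bad <- interval_counts(c(0, 0.5), c(0.5, 1), events = c(-4, 5),
                         censorships = c(5, 1), n_at_risk_start = c(10, 9),
                         residual_at_risk = 0, report_interval = c(1L, 1L))
  expect_error(clean_counts(bad), "inconsistent")
  expect_silent(clean_counts(bad, max_adjust = 0.5))
})

test_that("cleaned noisy reconstructions satisfy all count invariants", {
  set.seed(99)
  spec <- trial_spec(200, lambda = 0.1, gamma = 1)
  base <- summarize_trial(simulate_trial(spec, seed = 5), spec)
  for (i in 1:100) {
    s <- base$survival + runif(length(base$survival), -0.005, 0.005)
    s <- cummin(pmin(pmax(s, 1e-6), 1)); s[1] <- 1
    summ <- km_summary(base$risk_times, base$n_at_risk, base$grid_times, s)
    cnt <- reconstruct_ipd(summ, level = 3, max_adjust = 0.5)
    expect_true(all(cnt$events >= 0))
    expect_true(all(cnt$censorships >= 0))
    drop <- cnt$events + cnt$censorships
    expect_equal(cnt$n_at_risk_start[-1],
                 (cnt$n_at_risk_start - drop)[-nrow(cnt)], tolerance = 1e-9)
    expect_equal(sum(drop) + attr(cnt, "residual_at_risk"),
                 summ$n_at_risk[1], tolerance = 1e-9)
  }
})

test_that("monotonicity violations are rejected, not repaired", {
  expect_error(reconstruct_level1(c(1, 0.8, 0.85), c(100, 70, 60)),
               "non-increasing")
  expect_error(reconstruct_level1(c(1, 0.8, 0.7), c(100, 70, 80)),
               "non-increasing")
  expect_error(km_summary(c(0, 2), c(100, 110), c(0, .5, 1, 1.5, 2),
                          c(1, .9, .8, .7, .6)), "reporting time index 2")
})

test_that("a curve hitting zero assigns the remaining patients as events", {
  cnt <- reconstruct_level1(c(1, 0.4, 0), c(50, 18, 0), times = 0:2)
  expect_equal(cnt$events[2], 18)
  expect_equal(cnt$censorships[2], 0)
  expect_equal(sum(cnt$events) + sum(cnt$censorships), 50, tolerance = 1e-9)
})
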