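#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] that returns a step function
#' representation convenient for reading survival probabilities off a
#' regular grid.
#'
#' @param time Observed times (event or censoring), non-negative.
#' @param event Event indicator: 1/`TRUE` for an event, 0/`FALSE` censored.
#' @return An object of class `km_curve` with the step times and values.
#' @export
km_estimator <- function(time, event) {
  if (!length(time)) stop("no observations")
  if (any(time < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  structure(list(times = fit$time, surv = fit$surv,
                 n_events = sum(as.integer(event))),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Uses the right-continuous step convention, so the value at an event time
#' already includes the drop at that time; beyond the last observation the
#' last value is carried forward.
#'
#' @param curve A `km_curve` from [km_estimator()].
#' @param times Times at which to read the survival probability.
#' @return Survival probabilities at `times`.
#' @export
eval_km <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  f <- stats::stepfun(curve$times, c(1, curve$surv), right = FALSE)
  f(times)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$times), "distinct times,",
      x$n_events, "events; final S =",
      format(x$surv[length(x$surv)], digits = 4), "\n")
  invisible(x)
}

#' Weibull fit by least squares on the survival probabilities
#'
#' The traditional "least squares" method: chooses \eqn{(\lambda,\gamma)}
#' minimising \eqn{\sum_t (S(t) - e^{-\lambda t^\gamma})^2} over the grid
#' readings, all grid points weighted equally.
#'
#' @param times Grid times.
#' @param survival Survival probabilities at `times`.
#' @return Named vector `c(lambda, gamma)`.
#' @export
fit_least_squares <- function(times, survival) {
  if (length(times) != length(survival)) stop("length mismatch")
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]")
  obj <- function(p) sum((survival - exp(-p[1] * times^p[2]))^2)
  starts <- list(c(0.1, 1))
  reg <- tryCatch(fit_regression(times, survival), error = function(e) NULL)
  if (!is.null(reg) && all(is.finite(reg)) && all(reg > 0))
    starts <- c(list(unname(reg)), starts)
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = c(1e-8, 1e-8), upper = c(1e3, 1e3)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) stop("least-squares fit failed to converge")
  c(lambda = best$par[1], gamma = best$par[2])
}

#' Weibull fit by log-minus-log regression
#'
#' The traditional "regression" method: ordinary least squares of
#' \eqn{\log(-\log S(t))} on \eqn{\log t}. The slope estimates the shape
#' \eqn{\gamma} and the exponentiated intercept the rate \eqn{\lambda}
#' (the regression line is \eqn{\log\lambda + \gamma\log t}). Points with
#' \eqn{t = 0}, \eqn{S = 1} or \eqn{S = 0} carry no information on the
#' log-log scale and are dropped.
#'
#' @inheritParams fit_least_squares
#' @return Named vector `c(lambda, gamma)`.
#' @export
fit_regression <- function(times, survival) {
  if (length(times) != length(survival)) stop("length mismatch")
  ok <- times > 0 & survival > 0 & survival < 1
  if (sum(ok) < 2) stop("fewer than 2 usable points for log-log regression")
  x <- log(times[ok]); y <- log(-log(survival[ok]))
  co <- stats::lm.fit(cbind(1, x), y)$coefficients
  c(lambda = unname(exp(co[1])), gamma = unname(co[2]))
}

#' Weibull maximum likelihood on complete individual patient data
#'
#' The benchmark fit available only with the full data: maximises
#' \eqn{\sum_{events}\log f(t_i) + \sum_{censored}\log S(t_i)}. Reported in
#' the same form as [fit_mle()] so both routes feed the same downstream
#' summaries.
#'
#' @param time Observed times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param family A `surv_family` or family name.
#' @return A `km_fit` object.
#' @export
fit_ipd_mle <- function(time, event, family = "weibull") {
  fam <- as_surv_family(family)
  event <- as.integer(event)
  if (length(time) != length(event)) stop("length mismatch")
  if (sum(event) < 1) stop("no events in the data; cannot fit")
  t_ev <- time[event == 1]; t_cn <- time[event == 0]
  t_ev <- pmax(t_ev, 1e-12)  # avoid log(0) density at exact-zero times
  ll_fun <- function(theta) {
    par <- fam$from_opt(theta)
    if (!fam$in_domain(par)) return(-Inf)
    d <- fam$dens(t_ev, par)
    if (any(d <= 0) || any(!is.finite(d))) return(-Inf)
    ll <- sum(log(d))
    if (length(t_cn)) {
      s <- fam$surv(t_cn, par)
      if (any(s <= 0)) return(-Inf)
      ll <- ll + sum(log(s))
    }
    ll
  }
  # moment-style starts: exponential rate, then unit shape
  rate <- sum(event) / max(sum(time), 1e-12)
  starts <- switch(fam$name,
    weibull = list(c(rate, 1), c(rate, 0.7), c(rate, 1.5)),
    exponential = list(rate),
    loglogistic = list(c(rate, 1.2), c(rate, 2)),
    lognormal = list(c(mean(log(pmax(time, 1e-6))),
                       stats::sd(log(pmax(time, 1e-6))) + 0.1)))
  best <- optimise_loglik(ll_fun, fam$npar, starts, fam$to_opt)
  negll <- function(theta) {
    v <- ll_fun(theta)
    if (!is.finite(v)) 1e10 else -v
  }
  finish_fit(fam, best$par, negll, best$value, "complete-data MLE",
             best$n_starts)
}

#' Scale a Weibull rate by a hazard ratio
#'
#' Under a shared shape, multiplying the rate by the hazard ratio gives the
#' proportional-hazards transformed curve: \eqn{S_{new}(t) = S_{base}(t)^{hr}}.
#'
#' @param params Named or positional Weibull parameters `c(lambda, gamma)`.
#' @param hr Positive hazard ratio.
#' @return Transformed parameter vector `c(lambda, gamma)`.
#' @export
apply_hazard_ratio <- function(params, hr) {
  if (length(params) != 2) stop("expected c(lambda, gamma)")
  if (!is.finite(hr) || hr <= 0) stop("hazard ratio must be positive")
  c(lambda = unname(params[1] * hr), gamma = unname(params[2]))
}
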