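#' Reconstructed interval counts
#'
#' Holds the estimated numbers of events and censorships per time interval —
#' the pseudo individual patient data recovered from a summary Kaplan-Meier
#' graph. Counts are real-valued: the reconstruction equations rarely give
#' integers, and the fractional counts are used directly as likelihood
#' weights downstream.
#'
#' @param start,end Interval endpoints; intervals `[start, end)` tile the
#'   observation window.
#' @param events,censorships Estimated counts per interval (may be
#'   fractional, and negative before cleaning).
#' @param n_at_risk_start Reconstructed number at risk at each interval start.
#' @param residual_at_risk Patients still at risk at the last reporting time.
#' @param report_interval Integer index of the risk-reporting interval each
#'   sub-interval belongs to (used by [clean_counts()] to rebalance within a
#'   reporting interval).
#' @return An object of class `interval_counts`: a data frame with the above
#'   columns and attribute `residual_at_risk`.
#' @export
interval_counts <- function(start, end, events, censorships,
                            n_at_risk_start, residual_at_risk,
                            report_interval = seq_along(start)) {
  if (length(unique(c(length(start), length(end), length(events),
                      length(censorships), length(n_at_risk_start),
                      length(report_interval)))) != 1L)
    stop("all interval columns must have the same length")
  if (any(end <= start)) stop("intervals must have positive length")
  x <- data.frame(start = as.numeric(start), end = as.numeric(end),
                  events = as.numeric(events),
                  censorships = as.numeric(censorships),
                  n_at_risk_start = as.numeric(n_at_risk_start),
                  report_interval = as.integer(report_interval))
  attr(x, "residual_at_risk") <- as.numeric(residual_at_risk)
  class(x) <- c("interval_counts", "data.frame")
  x
}

#' @export
print.interval_counts <- function(x, digits = 4, ...) {
  cat("Reconstructed interval counts (", nrow(x), " intervals)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("residual at risk at t_max:",
      format(attr(x, "residual_at_risk"), digits = digits), "\n")
  rep_ <- attr(x, "cleaning")
  if (!is.null(rep_) && rep_$n_adjusted > 0)
    cat("cleaning: ", rep_$n_adjusted, " count(s) adjusted, total mass ",
        format(rep_$total_adjustment, digits = 3), "\n", sep = "")
  invisible(x)
}

residual_at_risk <- function(counts) attr(counts, "residual_at_risk")

check_sr <- function(S, R) {
  if (length(S) != length(R)) stop("S and R differ in length")
  if (length(S) < 2L) stop("need at least two time points")
  if (any(diff(S) > 1e-9)) stop("S must be non-increasing")
  if (any(diff(R) > 1e-9)) stop("R must be non-increasing")
  if (any(S < 0) || any(S > 1 + 1e-12)) stop("S must lie in [0, 1]")
  if (any(R < 0)) stop("R must be non-negative")
  if (any(S == 0 & R > 1e-9))
    stop("survival 0 with a positive number at risk is contradictory")
}

#' Events and censorships per reporting interval (coarsest reconstruction)
#'
#' Solves, for each risk-reporting interval, the pair of balance equations
#' that link the Kaplan-Meier survival probabilities to the numbers at risk
#' under the assumption that censoring occurs at a constant rate within the
#' interval. The solution is
#' \deqn{D = (R(t)+R(t+1))\,\frac{S(t)-S(t+1)}{S(t)+S(t+1)}, \qquad
#'       C = \frac{2\,(S(t+1)R(t) - S(t)R(t+1))}{S(t)+S(t+1)},}
#' which satisfies \eqn{D + C = R(t) - R(t+1)} exactly, so the at-risk
#' bookkeeping is conserved by construction.
#'
#' @param S Survival probabilities at the reporting times.
#' @param R Numbers at risk at the same times.
#' @param times Optional reporting times (defaults to `0, 1, 2, ...`).
#' @return An [interval_counts] object with one row per reporting interval.
#' @export
reconstruct_level1 <- function(S, R, times = seq_along(S) - 1) {
  check_sr(S, R)
  m <- length(S) - 1L
  D <- C <- numeric(m)
  for (k in seq_len(m)) {
    s0 <- S[k]; s1 <- S[k + 1]
    if (s0 <= 0) { D[k] <- 0; C[k] <- 0; next }
    if (s1 <= 0) { D[k] <- R[k]; C[k] <- 0; next }  # curve hits zero here
    D[k] <- (R[k] + R[k + 1]) * (s0 - s1) / (s0 + s1)
    C[k] <- 2 * (s1 * R[k] - s0 * R[k + 1]) / (s0 + s1)
  }
  interval_counts(times[-length(times)], times[-1], D, C,
                  n_at_risk_start = R[-length(R)],
                  residual_at_risk = R[length(R)],
                  report_interval = seq_len(m))
}

# Core of the half-interval solution: given survival at the start, midpoint
# and end of one reporting interval and the at-risk counts at its ends,
# return D(first half), D(second half), C(whole interval), R(midpoint).
solve_half_interval <- function(s0, sh, s1, R0, R1) {
  Q <- sh * s0 + sh * s1 + 2 * s0 * s1
  P <- (sh * R0 + sh * R1 + 2 * s0 * R1) / Q
  D2 <- (sh - s1) * P
  D1 <- R0 + 3 * R1 - (3 * s1 + sh) * P
  C <- R0 - R1 - D1 - D2
  list(D1 = D1, D2 = D2, C = C, Rhalf = R0 - D1 - C / 2)
}

# Quarter-interval event count: survival at the start, interior point and
# end of a half-interval, with at-risk counts at its ends (same algebraic
# form as solve_half_interval's second-half event count).
solve_quarter_events <- function(s0, sq, s1, R0, R1) {
  Q <- sq * s0 + sq * s1 + 2 * s0 * s1
  (sq - s1) * (sq * R0 + sq * R1 + 2 * s0 * R1) / Q
}

# Fallback when the curve reaches zero inside a reporting interval: once
# S = 0 no one can remain at risk, so censoring within the interval is
# unidentifiable; assign all remaining patients as events, apportioned by
# the drop in S across the sub-intervals.
waterfall_events <- function(s, R0) {
  if (s[1] <= 0) return(rep(0, length(s) - 1L))
  R0 * (-diff(s)) / s[1]
}

#' Events and censorships per half interval
#'
#' Refines [reconstruct_level1()] using the survival probabilities read at
#' the midpoint of each reporting interval. Censoring is still assumed
#' constant within the reporting interval; the interval's censorship total
#' is split equally across its two halves.
#'
#' @param S Survival probabilities at interval starts, midpoints and ends:
#'   for `m` reporting intervals a vector of length `2m + 1`.
#' @param R Numbers at risk at the `m + 1` reporting times.
#' @param times Optional reporting times (defaults to `0, 1, 2, ...`).
#' @return An [interval_counts] object with two rows per reporting interval.
#' @export
reconstruct_level2 <- function(S, R, times = seq_along(R) - 1) {
  m <- length(R) - 1L
  if (length(S) != 2L * m + 1L)
    stop("S must be read at starts, midpoints and ends: expected ",
         2L * m + 1L, " values")
  check_sr(S[seq(1, 2 * m + 1, by = 2)], R)
  if (any(diff(S) > 1e-9)) stop("S must be non-increasing")
  start <- end <- D <- C <- nstart <- numeric(2L * m)
  report <- rep(seq_len(m), each = 2L)
  n <- R[1]
  for (k in seq_len(m)) {
    s0 <- S[2 * k - 1]; sh <- S[2 * k]; s1 <- S[2 * k + 1]
    a <- times[k]; b <- times[k + 1]; mid <- (a + b) / 2
    if (s0 <= 0 || sh <= 0) {
      d <- waterfall_events(c(s0, sh, s1), R[k]); cc <- c(0, 0)
    } else {
      sol <- solve_half_interval(s0, sh, s1, R[k], R[k + 1])
      d <- c(sol$D1, sol$D2); cc <- c(sol$C / 2, sol$C / 2)
    }
    i <- c(2 * k - 1, 2 * k)
    start[i] <- c(a, mid); end[i] <- c(mid, b)
    D[i] <- d; C[i] <- cc
    nstart[i] <- c(n, n - d[1] - cc[1])
    n <- n - sum(d) - sum(cc)
  }
  interval_counts(start, end, D, C, nstart,
                  residual_at_risk = R[length(R)], report_interval = report)
}

#' Events and censorships per quarter interval (the default reconstruction)
#'
#' The finest reconstruction, using all four survival readings per
#' reporting interval. Event counts for the two interior quarters come from
#' the same balance equations as the half-interval solution applied within
#' each half (using the reconstructed midpoint at-risk count); the first and
#' third quarter counts are obtained by differencing, and the half-interval
#' censorship total is split equally across the four quarters.
#'
#' @param summary A [km_summary] object.
#' @return An [interval_counts] object with four rows per reporting
#'   interval, suitable for [fit_mle()].
#' @export
reconstruct_level3 <- function(summary) {
  if (!inherits(summary, "km_summary")) stop("summary must be a km_summary")
  R <- summary$n_at_risk
  times <- summary$risk_times
  S <- summary$survival
  m <- length(R) - 1L
  start <- end <- D <- C <- nstart <- numeric(4L * m)
  report <- rep(seq_len(m), each = 4L)
  n <- R[1]
  for (k in seq_len(m)) {
    i0 <- 4L * (k - 1L)
    s <- S[(i0 + 1):(i0 + 5)]            # S at t, t+1/4, ..., t+1
    a <- times[k]; b <- times[k + 1]
    qs <- a + (b - a) * c(0, 0.25, 0.5, 0.75)
    qe <- a + (b - a) * c(0.25, 0.5, 0.75, 1)
    if (s[1] <= 0 || s[2] <= 0 || s[3] <= 0 || s[4] <= 0) {
      d <- waterfall_events(s, R[k]); cc <- rep(0, 4)
    } else {
      half <- solve_half_interval(s[1], s[3], s[5], R[k], R[k + 1])
      d2 <- solve_quarter_events(s[1], s[2], s[3], R[k], half$Rhalf)
      d4 <- solve_quarter_events(s[3], s[4], s[5], half$Rhalf, R[k + 1])
      d <- c(half$D1 - d2, d2, half$D2 - d4, d4)
      cc <- rep(half$C / 4, 4)
    }
    i <- (i0 + 1):(i0 + 4)
    start[i] <- qs; end[i] <- qe
    D[i] <- d; C[i] <- cc
    nstart[i] <- n - cumsum(c(0, (d + cc)[-4]))
    n <- n - sum(d) - sum(cc)
  }
  interval_counts(start, end, D, C, nstart,
                  residual_at_risk = R[length(R)], report_interval = report)
}

#' Clip negative reconstructed counts while conserving patient totals
#'
#' Noisy survival readings can produce slightly negative event or censorship
#' counts. `clean_counts` clips negatives to zero and removes the same mass
#' from the other counts of the same risk-reporting interval (first from the
#' companion count of the same sub-interval, then proportionally across the
#' interval), so that events + censorships still account exactly for the
#' drop in the numbers at risk.
#'
#' @param counts An [interval_counts] object.
#' @param max_adjust Error if the mass adjusted within a reporting interval
#'   exceeds this fraction of the number at risk at the interval start;
#'   such a violation indicates internally inconsistent input.
#' @param tol Negative values no larger than this in magnitude are treated
#'   as numerical noise and rebalanced silently.
#' @return The cleaned [interval_counts], with a `cleaning` attribute
#'   listing the number of adjusted counts and the total adjusted mass.
#' @export
clean_counts <- function(counts, max_adjust = 0.1, tol = 1e-6) {
  stopifnot(inherits(counts, "interval_counts"))
  x <- counts
  n_adj <- 0L; total_adj <- 0
  for (g in unique(x$report_interval)) {
    i <- which(x$report_interval == g)
    d <- x$events[i]; cc <- x$censorships[i]
    if (all(d >= 0) && all(cc >= 0)) next
    deficit <- -(sum(pmin(d, 0)) + sum(pmin(cc, 0)))
    sig <- sum(d < -tol) + sum(cc < -tol)
    n_adj <- n_adj + sig
    if (deficit > tol) total_adj <- total_adj + deficit
    R0 <- x$n_at_risk_start[i[1]]
    if (deficit > max_adjust * R0)
      stop("cleaning would move ", format(deficit, digits = 3),
           " patients in reporting interval ", g, " (more than ",
           format(100 * max_adjust), "% of the ", R0, " at risk); ",
           "the survival and at-risk inputs are inconsistent")
    # clip, taking the mass first from the companion count in the same row
    for (j in seq_along(d)) {
      if (d[j] < 0) {
        take <- min(cc[j], -d[j]); cc[j] <- cc[j] - take
        deficit <- deficit - take; d[j] <- 0
      }
      if (cc[j] < 0) {
        take <- min(d[j], -cc[j]); d[j] <- d[j] - take
        deficit <- deficit - take; cc[j] <- 0
      }
    }
    # spread any remainder proportionally over the interval's positive counts
    while (deficit > 1e-12) {
      pool <- c(d, cc); tot <- sum(pool)
      if (tot <= deficit + 1e-12) { d[] <- 0; cc[] <- 0; break }
      red <- pool / tot * deficit
      red <- pmin(red, pool)
      d <- d - red[seq_along(d)]
      cc <- cc - red[seq_along(cc) + length(d)]
      deficit <- deficit - sum(red)
    }
    x$events[i] <- d; x$censorships[i] <- cc
  }
  # recompute the running at-risk counts from the cleaned flows
  n <- x$n_at_risk_start[1]
  drop <- x$events + x$censorships
  x$n_at_risk_start <- n - cumsum(c(0, drop[-length(drop)]))
  attr(x, "cleaning") <- list(n_adjusted = n_adj, total_adjustment = total_adj)
  x
}

#' Reconstruct pseudo individual patient data from a Kaplan-Meier summary
#'
#' Convenience wrapper: runs the reconstruction at the requested refinement
#' level and cleans the result. Level 3 (quarter intervals) is the default
#' and the recommended entry point.
#'
#' @param summary A [km_summary] object.
#' @param level Refinement level: 1 (reporting intervals), 2 (halves) or
#'   3 (quarters).
#' @param clean Apply [clean_counts()] to the raw counts (default `TRUE`).
#' @param max_adjust Passed to [clean_counts()].
#' @return An [interval_counts] object.
#' @export
reconstruct_ipd <- function(summary, level = 3, clean = TRUE,
                            max_adjust = 0.1) {
  stopifnot(inherits(summary, "km_summary"), level %in% 1:3)
  idx <- match_times(summary$risk_times, summary$grid_times)
  raw <- switch(level,
    reconstruct_level1(summary$survival[idx], summary$n_at_risk,
                       summary$risk_times),
    {
      half_idx <- sort(unique(c(idx, idx[-length(idx)] + 2L)))
      reconstruct_level2(summary$survival[half_idx], summary$n_at_risk,
                         summary$risk_times)
    },
    reconstruct_level3(summary))
  if (clean) clean_counts(raw, max_adjust = max_adjust) else raw
}
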