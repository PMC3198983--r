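#' Summary Kaplan-Meier data
#'
#' Container for the published summary of a single trial arm: survival
#' probabilities read off the Kaplan-Meier graph on a fine grid (four
#' readings per risk-reporting interval plus the final endpoint) and the
#' numbers of patients at risk printed beneath the graph.
#'
#' @param risk_times Ordered times at which numbers at risk are reported,
#'   starting at the origin of the curve.
#' @param n_at_risk Non-negative, non-increasing numbers at risk, one per
#'   `risk_times`; the first entry is the arm's sample size.
#' @param grid_times Reading times: for each reporting interval its start,
#'   1/4, 1/2, 3/4 points, plus the final reporting time.
#' @param survival Survival probabilities in `[0, 1]` at each grid time,
#'   non-increasing.
#' @return An object of class `km_summary`.
#' @seealso [read_km_summary()], [reconstruct_level3()]
#' @export
km_summary <- function(risk_times, n_at_risk, grid_times, survival) {
  risk_times <- as.numeric(risk_times)
  n_at_risk <- as.numeric(n_at_risk)
  grid_times <- as.numeric(grid_times)
  survival <- as.numeric(survival)

  if (length(risk_times) < 2L)
    stop("need at least two risk-reporting times")
  if (length(risk_times) != length(n_at_risk))
    stop("risk_times and n_at_risk differ in length")
  if (length(grid_times) != length(survival))
    stop("grid_times and survival differ in length")
  if (any(diff(risk_times) <= 0))
    stop("risk_times must be strictly increasing")
  bad <- which(diff(n_at_risk) > 1e-9)
  if (length(bad))
    stop("n_at_risk increases at reporting time index ", bad[1] + 1L,
         " (t = ", risk_times[bad[1] + 1L], "); numbers at risk must be ",
         "non-increasing")
  if (any(n_at_risk < 0)) stop("n_at_risk must be non-negative")
  if (n_at_risk[1] <= 0) stop("number at risk at the first reporting time ",
                              "must be positive")
  if (any(survival < -1e-12 | survival > 1 + 1e-12))
    stop("survival probabilities must lie in [0, 1]")
  bad <- which(diff(survival) > 1e-9)
  if (length(bad))
    stop("survival increases at grid index ", bad[1] + 1L, " (t = ",
         grid_times[bad[1] + 1L], "); survival must be non-increasing")

  expected <- quarter_grid(risk_times)
  if (length(grid_times) != length(expected) ||
      any(abs(grid_times - expected) > 1e-8))
    stop("grid_times must contain the start, 1/4, 1/2 and 3/4 points of ",
         "every reporting interval plus the final reporting time (",
         length(expected), " readings for these risk_times)")

  # survival of zero with patients still at risk is contradictory input
  s_at_risk <- survival[match_times(risk_times, grid_times)]
  bad <- which(s_at_risk <= 0 & n_at_risk > 0)
  if (length(bad))
    stop("survival is 0 at reporting time t = ", risk_times[bad[1]],
         " but the number at risk there is positive")

  structure(
    list(risk_times = risk_times, n_at_risk = n_at_risk,
         grid_times = expected, survival = pmin(pmax(survival, 0), 1)),
    class = "km_summary")
}

# quarter-point reading grid implied by the reporting times
quarter_grid <- function(risk_times) {
  starts <- risk_times[-length(risk_times)]
  len <- diff(risk_times)
  fracs <- c(0, 0.25, 0.5, 0.75)
  c(rep(starts, each = 4L) + rep(len, each = 4L) * fracs,
    risk_times[length(risk_times)])
}

match_times <- function(times, grid) {
  idx <- vapply(times, function(t) {
    j <- which(abs(grid - t) <= 1e-8 + 1e-8 * abs(t))
    if (!length(j)) NA_integer_ else j[1]
  }, integer(1))
  if (anyNA(idx)) stop("time not found on the reading grid")
  idx
}

#' @export
print.km_summary <- function(x, ...) {
  cat("Summary Kaplan-Meier data\n")
  cat("  reporting times:", paste(x$risk_times, collapse = ", "), "\n")
  cat("  numbers at risk:", paste(x$n_at_risk, collapse = ", "), "\n")
  cat("  ", length(x$grid_times), "survival readings, S(t_max) =",
      format(x$survival[length(x$survival)], digits = 4), "\n")
  invisible(x)
}
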