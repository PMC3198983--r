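#' Read summary Kaplan-Meier data from delimited text
#'
#' Expects two CSV files (UTF-8, header row, decimal point): the fine-grid
#' survival readings with columns `time,survival`, and the numbers at risk
#' with columns `time,n_risk`. Validation errors name the offending row of
#' the input file (header is row 1).
#'
#' @param grid_file CSV of grid times and survival probabilities.
#' @param risk_file CSV of reporting times and numbers at risk.
#' @return A [km_summary] object.
#' @export
read_km_summary <- function(grid_file, risk_file) {
  grid <- read_checked(grid_file, c("time", "survival"))
  risk <- read_checked(risk_file, c("time", "n_risk"))

  bad <- which(diff(grid$survival) > 1e-9)
  if (length(bad))
    stop(basename(grid_file), ": survival increases at row ",
         bad[1] + 2L, " (time ", grid$time[bad[1] + 1L], ")")
  bad <- which(diff(risk$n_risk) > 1e-9)
  if (length(bad))
    stop(basename(risk_file), ": n_risk increases at row ",
         bad[1] + 2L, " (time ", risk$time[bad[1] + 1L], ")")
  km_summary(risk$time, risk$n_risk, grid$time, grid$survival)
}

read_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols))
    stop(basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(x[[cl]]))
    bad <- which(is.na(v) & !is.na(x[[cl]]) | is.na(x[[cl]]))
    if (length(bad))
      stop(basename(path), ": malformed value in column '", cl,
           "' at row ", bad[1] + 1L)
    x[[cl]] <- v
  }
  x[cols]
}

#' Write summary Kaplan-Meier data to CSV
#'
#' Inverse of [read_km_summary()]; the written files round-trip to an
#' identical object.
#'
#' @param summary A [km_summary].
#' @inheritParams read_km_summary
#' @export
write_km_summary <- function(summary, grid_file, risk_file) {
  stopifnot(inherits(summary, "km_summary"))
  utils::write.csv(data.frame(time = summary$grid_times,
                              survival = summary$survival),
                   grid_file, row.names = FALSE)
  utils::write.csv(data.frame(time = summary$risk_times,
                              n_risk = summary$n_at_risk),
                   risk_file, row.names = FALSE)
  invisible(summary)
}

#' Write reconstructed interval counts to CSV
#'
#' Columns `interval_start,interval_end,events,censorships,n_at_risk_start`;
#' a final row with empty `interval_end` carries the residual number at
#' risk at the last reporting time.
#'
#' @param counts An [interval_counts] object.
#' @param path Output CSV path.
#' @export
write_interval_counts <- function(counts, path) {
  stopifnot(inherits(counts, "interval_counts"))
  out <- data.frame(interval_start = counts$start,
                    interval_end = counts$end,
                    events = counts$events,
                    censorships = counts$censorships,
                    n_at_risk_start = counts$n_at_risk_start)
  out <- rbind(out, data.frame(
    interval_start = counts$end[nrow(counts)], interval_end = NA_real_,
    events = NA_real_, censorships = NA_real_,
    n_at_risk_start = residual_at_risk(counts)))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(counts)
}

#' Read reconstructed interval counts from CSV
#'
#' @param path CSV written by [write_interval_counts()] (or following the
#'   same schema).
#' @return An [interval_counts] object. Reporting-interval membership is
#'   inferred from contiguous runs of sub-intervals between integer breaks
#'   in `n_at_risk_start`; if absent, each sub-interval is its own group.
#' @export
read_interval_counts <- function(path) {
  x <- read_checked_counts(path)
  n <- nrow(x)
  last <- x[n, ]
  if (!is.na(last$interval_end))
    stop(basename(path), ": final row must carry only the residual ",
         "number at risk (empty interval_end)")
  body <- x[-n, ]
  interval_counts(body$interval_start, body$interval_end, body$events,
                  body$censorships, body$n_at_risk_start,
                  residual_at_risk = last$n_at_risk_start,
                  report_interval = seq_len(n - 1L))
}

read_checked_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("interval_start", "interval_end", "events", "censorships",
            "n_at_risk_start")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop(basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in need) x[[cl]] <- suppressWarnings(as.numeric(x[[cl]]))
  x[need]
}

#' Configuration for an end-to-end curve-fitting run
#'
#' @param grid_file,risk_file Input CSVs, as for [read_km_summary()].
#' @param level Reconstruction refinement level (default 3).
#' @param families Distribution families to fit and compare.
#' @param alpha AIC penalty per parameter (default 2).
#' @param n_draws Parameter draws for the standard error of the mean.
#' @param seed Seed used for the parameter sampling.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param format `"csv"` or `"json"` for the fit report.
#' @param verbose Log progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(grid_file, risk_file, level = 3,
                       families = c("weibull", "exponential", "loglogistic",
                                    "lognormal"),
                       alpha = 2, n_draws = 10000, seed = 1,
                       out_dir = NULL, format = c("csv", "json"),
                       verbose = FALSE) {
  format <- match.arg(format)
  known <- c("weibull", "exponential", "loglogistic", "lognormal")
  bad <- setdiff(families, known)
  if (length(bad))
    stop("unknown distribution family: ", paste(bad, collapse = ", "))
  for (f in c(grid_file, risk_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  stopifnot(level %in% 1:3, alpha > 0, n_draws >= 2)
  structure(list(grid_file = grid_file, risk_file = risk_file,
                 level = level, families = families, alpha = alpha,
                 n_draws = n_draws, seed = as.integer(seed),
                 out_dir = out_dir, format = format, verbose = verbose),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  core <- config[c("level", "families", "alpha", "n_draws", "seed")]
  core$grid <- basename(config$grid_file)
  core$risk <- basename(config$risk_file)
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: reconstruct, fit, select, report
#'
#' Reads the summary Kaplan-Meier data, reconstructs the pseudo individual
#' patient data at the configured refinement level, cleans it, fits every
#' requested distribution family by interval-censored maximum likelihood,
#' selects the best by AIC and assembles a reproducible fit report
#' (estimates, covariance, Cholesky factor, mean survival and its standard
#' error, AIC table). Every output embeds the package version, a hash of
#' the configuration and the seed.
#'
#' @param config A [run_config].
#' @return An object of class `km_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  note <- function(...) if (config$verbose) message(...)

  note("reading: ", config$grid_file, " + ", config$risk_file)
  summ <- read_km_summary(config$grid_file, config$risk_file)

  note("reconstructing at level ", config$level)
  counts <- reconstruct_ipd(summ, level = config$level, clean = FALSE)
  counts <- clean_counts(counts)
  cl <- attr(counts, "cleaning")
  if (cl$n_adjusted > 0)
    note("cleaning adjusted ", cl$n_adjusted, " count(s), total mass ",
         format(cl$total_adjustment, digits = 3))

  fits <- lapply(config$families, function(f) {
    note("fitting ", f)
    fit_mle(counts, f)
  })
  names(fits) <- config$families
  best <- select_best(fits, alpha = config$alpha)
  note("selected: ", best$family)

  se <- tryCatch(se_of_mean(best, config$n_draws, seed = config$seed),
                 error = function(e) NA_real_)
  aic_tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    npar = vapply(fits, `[[`, numeric(1), "npar"))
  aic_tab$criterion <- -2 * aic_tab$loglik + config$alpha * aic_tab$npar
  aic_tab <- aic_tab[order(aic_tab$criterion), ]

  report <- structure(
    list(package_version = as.character(utils::packageVersion("kmrecon")),
         config_hash = config_hash(config), seed = config$seed,
         summary = summ, counts = counts, fits = fits, best = best,
         aic_table = aic_tab, se_of_mean = se),
    class = "km_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, config$out_dir, config$format)
  }
  report
}

#' @export
print.km_report <- function(x, digits = 5, ...) {
  cat("kmrecon fit report (package ", x$package_version, ", seed ", x$seed,
      ", config ", substr(x$config_hash, 1, 8), ")\n", sep = "")
  cat("\nModel comparison:\n")
  print(x$aic_table, digits = digits, row.names = FALSE)
  cat("\nSelected model:\n")
  print(x$best, digits = digits)
  cat("SE of mean survival (parameter simulation):",
      format(x$se_of_mean, digits = digits), "\n")
  invisible(x)
}

report_lines <- function(report) {
  b <- report$best
  header <- c(package_version = report$package_version,
              config_hash = report$config_hash, seed = report$seed)
  v <- if (is.null(b$vcov)) matrix(NA_real_, b$npar, b$npar) else b$vcov
  L <- if (is.null(b$chol)) matrix(NA_real_, b$npar, b$npar) else b$chol
  list(header = header,
       family = b$family,
       estimates = as.list(b$par),
       se = if (is.null(b$vcov)) rep(NA_real_, b$npar) else sqrt(diag(v)),
       covariance = v,
       cholesky_lower_rowmajor = as.vector(t(L)),
       loglik = b$loglik, AIC = b$AIC,
       mean_survival = b$mean_survival,
       se_of_mean = report$se_of_mean,
       aic_table = report$aic_table)
}

write_report <- function(report, out_dir, format = "csv") {
  body <- report_lines(report)
  write_interval_counts(report$counts, file.path(out_dir, "counts.csv"))
  if (format == "json") {
    jsonlite::write_json(body, file.path(out_dir, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  } else {
    path <- file.path(out_dir, "fit_report.csv")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# package_version=", body$header[["package_version"]],
                      " config_hash=", body$header[["config_hash"]],
                      " seed=", body$header[["seed"]]), con)
    fields <- c(family = body$family,
                stats::setNames(unlist(body$estimates),
                                names(body$estimates)),
                stats::setNames(body$se, paste0("se_", names(body$estimates))),
                stats::setNames(as.vector(body$covariance),
                                paste0("vcov_", outer(names(body$estimates),
                                                      names(body$estimates),
                                                      paste, sep = "_"))),
                stats::setNames(body$cholesky_lower_rowmajor,
                                paste0("chol_", seq_along(
                                  body$cholesky_lower_rowmajor))),
                loglik = body$loglik, AIC = body$AIC,
                mean_survival = body$mean_survival,
                se_of_mean = body$se_of_mean)
    tab <- data.frame(quantity = names(fields), value = unname(fields))
    utils::write.table(tab, con, sep = ",", row.names = FALSE,
                       qmethod = "double")
  }
  invisible(report)
}
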