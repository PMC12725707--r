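# Calibration-curve fitting and concentration estimation. One file is one
# calibrant point; unknowns are interpolated from the per-compound curve.

.conc_units <- c("ng/ml", "ug/ml", "mg/ml", "pM", "nM", "uM", "µM", "mM", "M")

#' Impute a calibrant concentration from a file name
#'
#' Looks for the first token of the form number-immediately-followed-by-unit,
#' where the unit is one of pM, nM, uM, µM, mM, M, ng/ml, ug/ml, mg/ml
#' (case-insensitive; underscores and hyphens act as separators). The number
#' is returned in the unit as written — no unit conversion — with the unit
#' string attached as attribute `"unit"`. `NA` signals no match.
#'
#' @param filename File name, e.g. `"std_100uM_r1.mzML"`.
#' @return Numeric concentration (attribute `unit`), or `NA_real_`.
#' @examples
#' impute_concentration_from_filename("std_100uM_r1.mzML")  # 100
#' impute_concentration_from_filename("blank.mzML")         # NA
#' @export
impute_concentration_from_filename <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L)
  units_re <- paste(
    vapply(.conc_units, function(u) gsub("/", "/", u, fixed = TRUE), character(1)),
    collapse = "|"
  )
  # unit must not run into further letters ("2Methyl" is not 2 M)
  re <- sprintf("(?i)([0-9]+(?:\\.[0-9]+)?)(%s)(?![A-Za-z])", units_re)
  m <- regexpr(re, filename, perl = TRUE)
  if (m[1] == -1L) return(NA_real_)
  token <- regmatches(filename, m)
  num <- as.numeric(sub(re, "\\1", token, perl = TRUE))
  unit <- sub(re, "\\2", token, perl = TRUE)
  structure(num, unit = unit)
}

#' Fit a calibration curve
#'
#' Ordinary (unweighted) least squares of integrated response against known
#' concentration, either on the raw scales (`"linear"`) or after log10 of
#' both axes (`"loglog"`, the usual choice for serial dilutions spanning
#' several decades).
#'
#' @param points Tibble with columns `concentration`, `response` and
#'   optionally `source_file`; one calibrant file contributes one point.
#' @param scale `"linear"` or `"loglog"`.
#' @param compound Compound name carried on the curve.
#' @param response_source `"MS"` or `"LC"`, recorded for provenance.
#' @return A `calibration_curve` object: slope, intercept, `r_squared`, the
#'   underlying [stats::lm] fit, scale and the calibrant points. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
fit_calibration <- function(points, scale = c("linear", "loglog"),
                            compound = NA_character_,
                            response_source = c("MS", "LC")) {
  scale <- match.arg(scale)
  response_source <- match.arg(response_source)
  points <- tibble::as_tibble(points)
  stopifnot(all(c("concentration", "response") %in% names(points)))
  if (nrow(points) < 2L || length(unique(points$concentration)) < 2L) {
    stop_xq("degenerate_design", "need >= 2 points at >= 2 distinct concentrations")
  }
  if (scale == "loglog" && (any(points$concentration <= 0) || any(points$response <= 0))) {
    stop_xq("nonpositive_value", "log-log fitting needs positive concentrations and responses")
  }
  x <- points$concentration
  y <- points$response
  if (scale == "loglog") { x <- log10(x); y <- log10(y) }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(
      compound = compound,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      scale = scale,
      response_source = response_source,
      points = points,
      fit = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: %s response = %.6g * conc %+.6g  (R^2 = %.4f, %d points, %s scale)\n",
    x$compound, x$response_source, x$slope, x$intercept, x$r_squared,
    nrow(x$points), x$scale
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient table of a calibration curve
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy calibration_curve
#' @export
tidy.calibration_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients  # exact fits warn in summary.lm
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' One-row summary of a calibration curve
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with `compound`, `slope`, `intercept`, `r.squared`, `scale`,
#'   `response_source`, `n_points`.
#' @method glance calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, scale = x$scale,
    response_source = x$response_source, n_points = nrow(x$points)
  )
}

#' Estimate a concentration from a measured response
#'
#' Inverts the calibration line: `(response - intercept) / slope` on the
#' linear scale, `10^((log10 response - intercept) / slope)` on the log-log
#' scale. Estimates outside the calibrated concentration range are still
#' returned but carry attribute `extrapolated = TRUE` so callers can flag
#' them.
#'
#' @param curve A `calibration_curve`.
#' @param response Measured integrated response (must be > 0 for log-log).
#' @return Estimated concentration (attribute `extrapolated`).
#' @export
estimate_concentration <- function(curve, response) {
  if (curve$slope == 0) stop_xq("zero_slope", "calibration curve has zero slope")
  est <- if (curve$scale == "loglog") {
    if (response <= 0) stop_xq("nonpositive_value", "log-log inversion needs response > 0")
    10^((log10(response) - curve$intercept) / curve$slope)
  } else {
    (response - curve$intercept) / curve$slope
  }
  rng <- range(curve$points$concentration)
  structure(est, extrapolated = is.na(est) || est < rng[1] || est > rng[2])
}

#' Quantify integrated results against calibration files
#'
#' Takes the per-(file, ion) integration table produced by the pipeline,
#' designates calibrant files (explicitly, or by imputing concentrations from
#' file names), fits one calibration curve per compound from the calibrants'
#' integrated responses — a compound's response in a file is the sum over its
#' declared ions — and fills in estimated concentrations for all other files.
#' Calibrant records echo their known concentration rather than a re-estimate.
#' A compound whose calibration is degenerate is reported without
#' concentrations (with a warning) and does not affect other compounds.
#'
#' @param results Tibble with one row per (file, ion): columns `filename`,
#'   `compound`, `ion_name`, `mz`, `description`, `retention_time`,
#'   `ms_intensity`, `lc_intensity`.
#' @param calibration Either the string `"from-filename"` (impute known
#'   concentrations via [impute_concentration_from_filename()]) or a tibble
#'   with columns `filename`, `concentration` mapping calibrant files to
#'   known values. At most one concentration per file.
#' @param response_source `"MS"` (use `ms_intensity`) or `"LC"`
#'   (`lc_intensity`).
#' @param scale Calibration scale, `"linear"` (default) or `"loglog"`.
#' @return A list with `records` (quant-record tibble ready for
#'   [write_quant_csv()], one row per input row) and `curves` (named list of
#'   `calibration_curve` objects per compound).
#' @export
quantify <- function(results, calibration = "from-filename",
                     response_source = c("MS", "LC"),
                     scale = c("linear", "loglog")) {
  response_source <- match.arg(response_source)
  scale <- match.arg(scale)
  results <- tibble::as_tibble(results)
  resp_col <- if (response_source == "MS") "ms_intensity" else "lc_intensity"

  known <- .resolve_calibration(results, calibration)

  by_file <- results |>
    dplyr::group_by(.data$filename, .data$compound) |>
    dplyr::summarise(response = sum(.data[[resp_col]]), .groups = "drop") |>
    dplyr::left_join(known, by = "filename")

  curves <- list()
  est_map <- list()
  for (cmp in unique(results$compound)) {
    sub <- by_file[by_file$compound == cmp, , drop = FALSE]
    cal <- sub[!is.na(sub$concentration), , drop = FALSE]
    curve <- tryCatch(
      fit_calibration(
        tibble::tibble(concentration = cal$concentration, response = cal$response,
                       source_file = cal$filename),
        scale = scale, compound = cmp, response_source = response_source
      ),
      xq_error = function(e) {
        warning(sprintf("compound '%s': calibration not fitted (%s)",
                        cmp, conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    curves[[cmp]] <- curve
    est <- stats::setNames(rep(NA_real_, nrow(sub)), sub$filename)
    flag <- stats::setNames(rep(FALSE, nrow(sub)), sub$filename)
    for (j in seq_len(nrow(sub))) {
      if (!is.na(sub$concentration[j])) {
        est[j] <- sub$concentration[j]  # calibrant: echo the known value
      } else if (!is.null(curve)) {
        e <- tryCatch(estimate_concentration(curve, sub$response[j]),
                      xq_error = function(err) NA_real_)
        est[j] <- as.numeric(e)
        flag[j] <- isTRUE(attr(e, "extrapolated"))
      }
    }
    est_map[[cmp]] <- list(est = est, flag = flag)
  }

  records <- results
  records$concentration <- NA_real_
  for (i in seq_len(nrow(records))) {
    em <- est_map[[records$compound[i]]]
    records$concentration[i] <- em$est[[records$filename[i]]]
    if (isTRUE(em$flag[[records$filename[i]]])) {
      note <- "extrapolated beyond calibrated range"
      records$description[i] <- if (is.na(records$description[i])) note else
        paste(records$description[i], note, sep = "; ")
    }
  }
  records <- records[, c("filename", "ion_name", "mz", "description",
                         "retention_time", "ms_intensity", "lc_intensity",
                         "concentration")]
  list(records = records, curves = curves)
}

# Known concentrations per file: from a mapping table or filename imputation.
# Enforces the one-concentration-per-file rule.
.resolve_calibration <- function(results, calibration) {
  files <- unique(results$filename)
  if (is.character(calibration) && length(calibration) == 1L &&
      calibration == "from-filename") {
    conc <- vapply(files, function(f)
      as.numeric(impute_concentration_from_filename(f)), numeric(1))
    return(tibble::tibble(filename = files, concentration = unname(conc)))
  }
  calibration <- tibble::as_tibble(calibration)
  stopifnot(all(c("filename", "concentration") %in% names(calibration)))
  dup <- calibration |>
    dplyr::distinct(.data$filename, .data$concentration) |>
    dplyr::count(.data$filename) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop_xq("multiple_concentrations",
            paste("only one concentration value per file is supported;",
                  "offending file(s):", paste(dup$filename, collapse = ", ")))
  }
  missing_files <- setdiff(calibration$filename, files)
  if (length(missing_files)) {
    stop_xq("missing_calibrant",
            paste("calibrant file(s) absent from results:",
                  paste(missing_files, collapse = ", ")))
  }
  out <- tibble::tibble(filename = files)
  dplyr::left_join(out, dplyr::distinct(calibration), by = "filename")
}
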