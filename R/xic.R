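# Extracted ion chromatograms: ppm/dalton windows around user-declared ion
# m/z values, deduplicated across compounds, summed per scan via binary
# search over the sorted m/z array (O(U * S * log M) overall).

#' Mass tolerance specification
#'
#' @param ppm Half-width in parts-per-million of the window centre (the
#'   conventional default is 3 ppm).
#' @param da Half-width in daltons (e.g. 0.0003 for a +/- 0.0003 Da window).
#'   Exactly one of `ppm`/`da` must be given.
#' @return A list with elements `mode` (`"ppm"` or `"dalton"`) and `value`.
#' @export
mass_tol <- function(ppm = NULL, da = NULL) {
  if (is.null(ppm) == is.null(da)) {
    stop_xq("bad_tolerance", "specify exactly one of ppm= or da=")
  }
  value <- if (is.null(da)) ppm else da
  if (!is.numeric(value) || value <= 0) stop_xq("bad_tolerance", "tolerance must be > 0")
  list(mode = if (is.null(da)) "ppm" else "dalton", value = as.numeric(value))
}

#' Build deduplicated m/z windows from ion targets
#'
#' Each distinct ion m/z (distinct after rounding to 1e-6 Th, a
#' floating-point-safe notion of "the same ion") becomes one window; compounds
#' declaring the same ion share it, so a run is never re-scanned for an
#' identical m/z. The number of windows U is therefore at most the total
#' number of declared (compound, ion) pairs. Tolerances are half-widths:
#' in ppm mode `low/high = centre * (1 -/+ value * 1e-6)`, in dalton mode
#' `low/high = centre -/+ value`.
#'
#' @param targets Tibble of ion targets: one row per (compound, ion) with
#'   columns `compound`, `mz`, and optionally `description`, `expected_rt`.
#' @param tol A [mass_tol()] (default 3 ppm).
#' @return Tibble of class `ion_windows`: columns `window_id`, `center`,
#'   `low`, `high`, `owners` (list-column of tibbles with the owning
#'   `compound`, `mz`, `description`, `expected_rt` rows).
#' @export
build_windows <- function(targets, tol = mass_tol(ppm = 3)) {
  targets <- tibble::as_tibble(targets)
  stopifnot(all(c("compound", "mz") %in% names(targets)), nrow(targets) > 0)
  if (any(targets$mz <= 0)) stop_xq("bad_target", "ion m/z values must be > 0")
  if (!"description" %in% names(targets)) targets$description <- NA_character_
  if (!"expected_rt" %in% names(targets)) targets$expected_rt <- NA_real_
  key <- round(targets$mz, 6)
  centers <- sort(unique(key))
  owners <- lapply(centers, function(cc) targets[key == cc, , drop = FALSE])
  half <- switch(tol$mode,
    ppm = centers * tol$value * 1e-6,
    dalton = rep(tol$value, length(centers))
  )
  out <- tibble::tibble(
    window_id = seq_along(centers),
    center = centers,
    low = centers - half,
    high = centers + half,
    owners = owners
  )
  class(out) <- c("ion_windows", class(out))
  out
}

#' Summed intensity of one scan inside an m/z window
#'
#' Locates the first array index with `mz >= low` by binary search (the m/z
#' array is sorted) and sums intensities up to the last index with
#' `mz <= high`. Both interval endpoints are closed. Returns 0 when nothing
#' falls inside.
#'
#' @param mz Ascending numeric m/z array of one scan.
#' @param intensity Aligned intensity array.
#' @param low,high Window bounds (Th).
#' @return Scalar summed intensity.
#' @export
scan_window_intensity <- function(mz, intensity, low, high) {
  n <- length(mz)
  if (n == 0L) return(0)
  i1 <- findInterval(low, mz, left.open = TRUE) + 1L  # first index with mz >= low
  i2 <- findInterval(high, mz)                        # last index with mz <= high
  if (i1 > i2) return(0)
  sum(intensity[i1:i2])
}

#' Extract ion chromatograms for a set of windows
#'
#' Precomputes the run's scan metadata (retention-time axis, array handles)
#' once, then for every window sums each scan's intensity inside the window
#' bounds via [scan_window_intensity()]. All traces share the identical time
#' axis.
#'
#' @param run An `ms_run`.
#' @param windows An `ion_windows` tibble from [build_windows()].
#' @return Long tibble of class `xic_tbl`: one row per (window, scan) with
#'   columns `window_id`, `center`, `time`, `intensity`; attribute `windows`
#'   carries the window table and `source` the run identifier.
#' @export
extract_xics <- function(run, windows) {
  if (nrow(run) < 1L) stop_xq("empty_run", "run has no MS1 scans")
  times <- run$rt
  mzs <- run$mz
  ints <- run$intensity
  n_scans <- length(times)
  traces <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    lo <- windows$low[w]
    hi <- windows$high[w]
    y <- numeric(n_scans)
    for (k in seq_len(n_scans)) {
      y[k] <- scan_window_intensity(mzs[[k]], ints[[k]], lo, hi)
    }
    traces[[w]] <- tibble::tibble(
      window_id = windows$window_id[w],
      center = windows$center[w],
      time = times,
      intensity = y
    )
  }
  out <- dplyr::bind_rows(traces)
  attr(out, "windows") <- windows
  attr(out, "source") <- attr(run, "source")
  class(out) <- c("xic_tbl", class(out))
  out
}

#' Match XIC apexes to chromatography retention times
#'
#' For each trace, finds its apex (scan of maximal intensity; earliest scan on
#' ties) and matches it to the nearest reference retention time — manual peak
#' labels and/or the targets' expected retention times. Matches farther than
#' `rt_tol` minutes are reported unmatched (a valid outcome, not an error).
#' When two references are equidistant from the apex, the earlier retention
#' time wins.
#'
#' @param traces An `xic_tbl` from [extract_xics()].
#' @param chrom Optional [chromatogram()] from the same acquisition (used only
#'   to document the shared timeline; matching is by retention time).
#' @param labels Tibble with columns `name` and `retention_time` (e.g. from
#'   [read_peaklist()]), or `NULL` to use the windows' `expected_rt`.
#' @param rt_tol Maximal apex-to-label distance in minutes (default 0.5).
#' @return Tibble: `window_id`, `center`, `apex_time`, `apex_intensity`,
#'   `label_name`, `label_rt`, `matched`.
#' @export
annotate_with_chromatography <- function(traces, chrom = NULL, labels = NULL,
                                         rt_tol = 0.5) {
  windows <- attr(traces, "windows")
  if (is.null(labels)) {
    labels <- dplyr::bind_rows(lapply(seq_len(nrow(windows)), function(w) {
      own <- windows$owners[[w]]
      tibble::tibble(name = own$compound, retention_time = own$expected_rt)
    }))
    labels <- labels[!is.na(labels$retention_time), , drop = FALSE]
  }
  per_window <- function(df) {
    apex <- which.max(df$intensity)  # earliest scan on ties
    apex_t <- df$time[apex]
    res <- tibble::tibble(
      window_id = df$window_id[1], center = df$center[1],
      apex_time = apex_t, apex_intensity = df$intensity[apex],
      label_name = NA_character_, label_rt = NA_real_, matched = FALSE
    )
    if (nrow(labels) > 0) {
      d <- abs(labels$retention_time - apex_t)
      best <- order(d, labels$retention_time)[1]  # tie -> earlier RT
      if (d[best] <= rt_tol) {
        res$label_name <- labels$name[best]
        res$label_rt <- labels$retention_time[best]
        res$matched <- TRUE
      }
    }
    res
  }
  traces |>
    dplyr::group_by(.data$window_id) |>
    dplyr::group_split() |>
    purrr::map(per_window) |>
    dplyr::bind_rows()
}
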