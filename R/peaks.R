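# Retention-time-anchored peak boundary detection and trapezoidal
# integration, with a whole-trace fallback when no peak is found.

#' Find peak boundaries around a retention-time anchor
#'
#' Restricts the trace to `[anchor - rt_halfwindow, anchor + rt_halfwindow]`,
#' takes the apex as the maximum inside that region, then walks outward from
#' the apex in both directions. Each walk stops at the first of: the intensity
#' rising for two consecutive samples (boundary placed at the local valley —
#' robust to single-sample noise), or the intensity falling below 1% of the
#' apex height, or the end of the trace.
#'
#' @param times Numeric time axis (minutes), increasing.
#' @param intensities Aligned intensity vector.
#' @param anchor_rt Anchor retention time (minutes), e.g. an expected RT or a
#'   matched chromatography label.
#' @param rt_halfwindow Search half-window around the anchor (minutes,
#'   default 0.5 — typical LC peaks are well inside this).
#' @return A one-row tibble: `apex_index`, `left_index`, `right_index`,
#'   `anchor_rt` (indices are 1-based into the full trace,
#'   `left <= apex <= right`).
#' @export
find_peak_bounds <- function(times, intensities, anchor_rt, rt_halfwindow = 0.5) {
  stopifnot(length(times) == length(intensities), length(times) >= 2)
  region <- which(abs(times - anchor_rt) <= rt_halfwindow)
  if (!length(region) || all(intensities[region] == 0)) {
    stop_xq("no_signal", "no signal in the anchored retention-time window")
  }
  apex <- region[which.max(intensities[region])]
  h <- intensities[apex]
  floor_level <- 0.01 * h
  walk <- function(dir) {
    i <- apex
    rises <- 0L
    repeat {
      nxt <- i + dir
      if (nxt < 1L || nxt > length(intensities)) return(i)
      if (intensities[nxt] > intensities[i]) {
        rises <- rises + 1L
        if (rises >= 2L) return(i - dir)  # back off to the valley point
      } else {
        rises <- 0L
      }
      i <- nxt
      if (intensities[i] < floor_level) return(i)
    }
  }
  tibble::tibble(
    apex_index = apex,
    left_index = walk(-1L),
    right_index = walk(1L),
    anchor_rt = anchor_rt
  )
}

#' Integrate a bounded peak above a local linear baseline
#'
#' Subtracts the straight line through the two boundary points (a local
#' baseline appropriate for a narrow slice, where the long-context SNIP
#' estimator has nothing to work with) and integrates the remainder by the
#' trapezoidal rule over `[left, right]`. Negative net areas are clipped to 0.
#'
#' @param times,intensities Aligned trace arrays.
#' @param bounds One-row tibble from [find_peak_bounds()].
#' @return Non-negative peak area (intensity x minutes).
#' @export
integrate_peak <- function(times, intensities, bounds) {
  l <- bounds$left_index
  r <- bounds$right_index
  stopifnot(l >= 1, r <= length(times), l <= bounds$apex_index, bounds$apex_index <= r)
  if (l == r) return(0)
  tt <- times[l:r]
  yy <- intensities[l:r]
  base <- if (tt[length(tt)] == tt[1]) {
    rep(yy[1], length(tt))
  } else {
    yy[1] + (yy[length(yy)] - yy[1]) * (tt - tt[1]) / (tt[length(tt)] - tt[1])
  }
  max(pracma::trapz(tt, yy - base), 0)
}

#' Trapezoidal integral of a whole trace
#'
#' The fallback response when no peak can be anchored: the raw intensities
#' are summed over time by the trapezoidal rule, with no baseline
#' subtraction.
#'
#' @param times,intensities Aligned trace arrays of length >= 2.
#' @return Trapezoidal area.
#' @export
integrate_total <- function(times, intensities) {
  if (length(times) < 2L || length(intensities) != length(times)) {
    stop_xq("too_short", "need aligned arrays of length >= 2")
  }
  pracma::trapz(times, intensities)
}

# Response for one trace: anchored peak integration when possible, else the
# whole-trace trapezoid. Guarantees a finite response for every (file, ion).
.integrate_with_fallback <- function(times, intensities, anchor_rt, rt_halfwindow = 0.5) {
  if (!is.na(anchor_rt)) {
    bounds <- tryCatch(
      find_peak_bounds(times, intensities, anchor_rt, rt_halfwindow),
      xq_no_signal = function(e) NULL
    )
    if (!is.null(bounds)) {
      return(list(area = integrate_peak(times, intensities, bounds),
                  rt = times[bounds$apex_index], anchored = TRUE))
    }
  }
  apex <- which.max(intensities)
  list(area = integrate_total(times, intensities),
       rt = if (length(times)) times[apex] else NA_real_, anchored = FALSE)
}
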