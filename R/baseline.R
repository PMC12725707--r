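# SNIP baseline estimation (statistical non-linear iterative peak clipping).
# The signal is compressed with the LLS operator, clipped iteratively against
# the mean of symmetric neighbours at growing distance, then decompressed.

#' Log-log-square-root (LLS) compression
#'
#' Elementwise `v = ln(ln(sqrt(S + 1) + 1) + 1)`. The operator compresses the
#' dynamic range of a detector signal so that tall peaks do not dominate the
#' iterative clipping filter; it is strictly increasing and exactly invertible
#' by [inverse_lls()].
#'
#' @param signal Numeric vector, all elements `>= 0` (shift the signal first;
#'   [snip_baseline()] does this automatically).
#' @return Numeric vector of compressed values.
#' @export
lls <- function(signal) {
  if (any(signal < 0)) {
    stop_xq("negative_input", "lls() requires a non-negative signal; shift it first")
  }
  log(log(sqrt(signal + 1) + 1) + 1)
}

#' Inverse of the LLS compression
#'
#' Exact algebraic inverse: `S = (exp(exp(v) - 1) - 1)^2 - 1`.
#'
#' @param v Numeric vector of compressed values, `>= 0`.
#' @return Numeric vector on the original signal scale.
#' @export
inverse_lls <- function(v) {
  if (any(v < 0)) {
    stop_xq("negative_input", "inverse_lls() requires non-negative compressed values")
  }
  (exp(exp(v) - 1) - 1)^2 - 1
}

#' SNIP baseline of a detector signal
#'
#' Estimates a smooth baseline under chromatographic (or XIC) peaks. The
#' signal is shifted to be non-negative, compressed with [lls()], then for
#' iteration `i = 1..iterations` each interior point is replaced by
#' `min(w(t), (w(t - i) + w(t + i)) / 2)` — the clipping window grows with the
#' iteration index. Points whose symmetric neighbours fall outside the array
#' are left unchanged at that iteration. The clipped signal is decompressed
#' with [inverse_lls()] and unshifted.
#'
#' Twenty iterations is the fixed default, sufficient for typical LC/GC runs
#' while keeping preprocessing cheap; wider baselines need more iterations
#' (the effective clipping half-width is `iterations` samples).
#'
#' @param signal Numeric vector; any real values (negative absorbances are
#'   handled by the internal shift).
#' @param iterations Number of clipping passes (default 20). Clamped, with a
#'   warning, to `floor((length(signal) - 1) / 2)` for short signals.
#' @return Numeric baseline vector, same length and units as `signal`.
#' @export
snip_baseline <- function(signal, iterations = 20L) {
  n <- length(signal)
  if (n < 2L) stop_xq("signal_too_short", "need at least 2 samples")
  iterations <- as.integer(iterations)
  max_iter <- (n - 1L) %/% 2L
  if (iterations > max_iter) {
    warning(sprintf("signal of length %d supports at most %d SNIP iterations; clamping",
                    n, max_iter), call. = FALSE)
    iterations <- max_iter
  }
  shift <- min(signal)
  w <- lls(signal - shift)
  for (i in seq_len(iterations)) {
    idx <- (i + 1L):(n - i)
    w[idx] <- pmin(w[idx], (w[idx - i] + w[idx + i]) / 2)
  }
  inverse_lls(pmax(w, 0)) + shift
}

#' Baseline-correct a chromatogram with SNIP
#'
#' Runs [snip_baseline()] on the trace and returns the input together with the
#' estimated baseline and the corrected signal; by construction
#' `corrected + baseline` reconstructs the input exactly.
#'
#' @param chrom A [chromatogram()].
#' @param iterations SNIP iterations (default 20).
#' @return A tibble of class `baseline_tbl` with columns `time`, `signal`,
#'   `baseline`, `corrected` and attribute `iterations`.
#' @export
correct_baseline <- function(chrom, iterations = 20L) {
  bl <- snip_baseline(chrom$signal, iterations = iterations)
  out <- tibble::tibble(
    time = chrom$time,
    signal = chrom$signal,
    baseline = bl,
    corrected = chrom$signal - bl
  )
  attr(out, "iterations") <- as.integer(iterations)
  attr(out, "label") <- attr(chrom, "label")
  class(out) <- c("baseline_tbl", class(out))
  out
}
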