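# mzML ingestion. Parsing, base64/zlib decoding and 32/64-bit float handling
# are delegated to mzR (proteowizard backend); this layer filters to MS1,
# normalises units and enforces the run invariants.

#' Read an mzML file into an MS1 run
#'
#' Loads all spectra, keeps MS1 scans only (MS2 and higher are discarded), and
#' returns them in acquisition order as a tibble of scans with list-columns for
#' the m/z and intensity arrays. Retention times are converted to minutes
#' (mzML declares its time unit explicitly; mzR reports seconds). Scans whose
#' m/z array violates ascending order are re-sorted with a warning, carrying
#' their intensities along. Scans lacking an MS level are treated as MS1 and
#' logged; scans lacking a retention time inherit the previous scan's time
#' plus the run's median scan interval.
#'
#' @param path Path to an mzML 1.1.x file (plain or indexed; 32/64-bit float
#'   arrays, optionally zlib-compressed).
#' @return An `ms_run`: a tibble with one row per MS1 scan and columns
#'   `index` (0-based ordinal after MS1 filtering), `rt` (minutes),
#'   `ms_level`, `injection_time` (ms, `NA` when absent), `mz` and
#'   `intensity` (list-columns of aligned numeric vectors); attribute
#'   `source` holds the file name.
#' @export
read_ms_run <- function(path) {
  if (!file.exists(path)) {
    stop_xq("unreachable_file", sprintf("cannot read mzML file '%s'", path))
  }
  handle <- tryCatch(
    mzR::openMSfile(path, backend = "pwiz"),
    error = function(e) stop_xq("malformed_xml", sprintf("'%s': %s", path, conditionMessage(e)))
  )
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) {
    warning(sprintf("'%s' contains no spectra", path), call. = FALSE)
    return(.ms_run(list(), basename(path)))
  }
  lvl <- hdr$msLevel
  if (anyNA(lvl) || any(lvl < 1)) {
    warning(sprintf("'%s': %d scan(s) without an MS level treated as MS1",
                    path, sum(is.na(lvl) | lvl < 1)), call. = FALSE)
    lvl[is.na(lvl) | lvl < 1] <- 1L
  }
  keep <- which(lvl == 1L)
  if (!length(keep)) {
    warning(sprintf("'%s' contains no MS1 scans", path), call. = FALSE)
    return(.ms_run(list(), basename(path)))
  }
  rt_min <- hdr$retentionTime[keep] / 60
  if (anyNA(rt_min)) {
    step <- stats::median(diff(rt_min[!is.na(rt_min)]))
    if (!is.finite(step)) step <- 0
    for (k in seq_along(rt_min)) {
      if (is.na(rt_min[k])) rt_min[k] <- if (k == 1L) 0 else rt_min[k - 1L] + step
    }
  }
  pk <- mzR::peaks(handle, keep)
  if (is.matrix(pk)) pk <- list(pk)
  unsorted <- 0L
  scans <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    m <- pk[[k]]
    mz <- as.numeric(m[, 1])
    inten <- as.numeric(m[, 2])
    if (is.unsorted(mz)) {
      unsorted <- unsorted + 1L
      o <- order(mz)
      mz <- mz[o]
      inten <- inten[o]
    }
    scans[[k]] <- list(mz = mz, intensity = inten)
  }
  if (unsorted > 0L) {
    warning(sprintf("'%s': %d scan(s) had non-ascending m/z arrays and were re-sorted",
                    path, unsorted), call. = FALSE)
  }
  inj <- hdr$injectionTime[keep]
  out <- tibble::tibble(
    index = seq_along(keep) - 1L,
    rt = rt_min,
    ms_level = 1L,
    injection_time = if (is.null(inj)) NA_real_ else as.numeric(inj),
    mz = lapply(scans, `[[`, "mz"),
    intensity = lapply(scans, `[[`, "intensity")
  )
  .as_ms_run(out, basename(path))
}

.ms_run <- function(scans, source) {
  out <- tibble::tibble(
    index = integer(), rt = numeric(), ms_level = integer(),
    injection_time = numeric(), mz = list(), intensity = list()
  )
  .as_ms_run(out, source)
}

.as_ms_run <- function(tbl, source) {
  bad <- which(lengths(tbl$mz) != lengths(tbl$intensity))
  if (length(bad)) {
    stop_xq("invalid_scan", "m/z and intensity arrays differ in length")
  }
  if (nrow(tbl) > 1L && any(diff(tbl$rt) < 0)) {
    stop_xq("invalid_run", "scan retention times must be non-decreasing")
  }
  attr(tbl, "source") <- source
  class(tbl) <- unique(c("ms_run", class(tbl)))
  tbl
}

#' Total ion current of an MS run
#'
#' Sums each scan's intensity array, yielding a chromatogram-like trace used
#' in place of a separation dimension for direct-infusion or flow-injection
#' data.
#'
#' @param run An `ms_run` from [read_ms_run()] or [gen_ms_run()].
#' @return A [chromatogram()] whose `time` axis is the scan retention times
#'   and whose `signal` is the per-scan intensity sum.
#' @export
total_ion_current <- function(run) {
  if (nrow(run) < 1L) stop_xq("empty_run", "run has no MS1 scans")
  sums <- vapply(run$intensity, function(x) sum(x), numeric(1))
  times <- run$rt
  if (nrow(run) == 1L) {
    # chromatogram needs >= 2 samples; duplicate the lone scan with an epsilon
    times <- c(times, times + 1e-9)
    sums <- c(sums, sums)
  } else if (any(diff(times) <= 0)) {
    # tied scan times (allowed in a run) are nudged apart for the trace axis
    times <- times + (seq_along(times) - 1) * 1e-9
  }
  chromatogram(times, sums, label = attr(run, "source"))
}
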