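# Text-table I/O for chromatography traces and long-format quant exports.

# Candidate delimiters, tried in this order. "" means any whitespace run.
.delim_candidates <- c(",", "\t", ";", "")

.split_row <- function(line, delim) {
  if (identical(delim, "")) {
    out <- strsplit(trimws(line), "[ \t]+")[[1]]
  } else {
    out <- strsplit(line, delim, fixed = TRUE)[[1]]
  }
  trimws(out)
}

.is_float_cell <- function(x) {
  nzchar(x) & !is.na(suppressWarnings(as.numeric(x)))
}

#' Detect the table dialect of a delimited chromatography file
#'
#' Scans the raw text for the first delimiter (tried in order: comma, tab,
#' semicolon, whitespace run) under which at least two consecutive rows parse
#' to two or more floating-point columns. Leading lines before the first such
#' row are treated as a header and skipped. Per the field convention for
#' exported detector traces, the *first* float column is taken as retention
#' time and the *last* float column as the detector signal.
#'
#' Decimal separator is the dot only; locales using comma decimals are not
#' supported (the comma is a delimiter candidate, so the two are ambiguous).
#'
#' @param raw_text Character scalar (or vector of lines) holding the file
#'   contents.
#' @return A one-row tibble with columns `delimiter` (`","`, `"\t"`, `";"` or
#'   `""` for a whitespace run), `header_lines`, `time_column` and
#'   `signal_column` (1-based column indices; always distinct).
#' @examples
#' sniff_dialect("rt,abs\n0.1,5.0\n0.2,6.0")
#' @export
sniff_dialect <- function(raw_text) {
  stopifnot(is.character(raw_text), length(raw_text) >= 1)
  lines <- if (length(raw_text) == 1L) strsplit(raw_text, "\r?\n")[[1]] else raw_text
  lines <- lines[!(seq_along(lines) == length(lines) & !nzchar(lines))]
  if (length(lines) < 2L) {
    stop_xq("no_parseable_table", "need at least two rows of data to sniff a table dialect")
  }
  for (delim in .delim_candidates) {
    float_cols_of <- function(line) {
      cells <- .split_row(line, delim)
      which(.is_float_cell(cells))
    }
    for (h in 0:(length(lines) - 2L)) {
      a <- float_cols_of(lines[h + 1L])
      b <- float_cols_of(lines[h + 2L])
      shared <- intersect(a, b)
      if (length(shared) >= 2L) {
        return(tibble::tibble(
          delimiter = delim,
          header_lines = h,
          time_column = min(shared),
          signal_column = max(shared)
        ))
      }
    }
  }
  stop_xq("no_parseable_table",
          "no delimiter candidate yields two float columns on two consecutive rows")
}

#' Read a chromatography trace from delimited text
#'
#' Parses a two-column (retention time, detector signal) trace using an
#' automatically sniffed dialect (see [sniff_dialect()]) or one supplied by the
#' caller. Rows after the header whose time or signal cell fails float
#' conversion (footer lines, embedded comments) are skipped with a warning.
#' Negative detector values (e.g. negative absorbance) are preserved
#' unchanged. Retention times are kept in file units — by convention minutes —
#' and never rescaled.
#'
#' @param path Path to a TXT/CSV trace file.
#' @param dialect Optional dialect tibble as returned by [sniff_dialect()].
#' @return A `chromatogram`: a tibble with numeric columns `time` and `signal`
#'   (strictly increasing `time`, at least two rows) and a `label` attribute
#'   identifying the source.
#' @export
read_chromatogram <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    stop_xq("unreachable_file", sprintf("cannot read chromatography file '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (is.null(dialect)) dialect <- sniff_dialect(lines)
  body <- lines[seq_along(lines) > dialect$header_lines]
  tc <- dialect$time_column
  sc <- dialect$signal_column
  parsed <- lapply(body, function(line) {
    cells <- .split_row(line, dialect$delimiter)
    if (length(cells) < max(tc, sc)) return(NULL)
    tv <- suppressWarnings(as.numeric(cells[tc]))
    sv <- suppressWarnings(as.numeric(cells[sc]))
    if (is.na(tv) || is.na(sv)) return(NULL)
    c(tv, sv)
  })
  bad <- vapply(parsed, is.null, logical(1)) & nzchar(trimws(body))
  if (any(bad)) {
    warning(sprintf("%d row(s) in '%s' failed float conversion and were skipped",
                    sum(bad), path), call. = FALSE)
  }
  keep <- parsed[!vapply(parsed, is.null, logical(1))]
  if (length(keep) < 2L) {
    stop_xq("no_parseable_table", sprintf("'%s': fewer than two parseable data rows", path))
  }
  m <- do.call(rbind, keep)
  chromatogram(m[, 1], m[, 2], label = basename(path))
}

#' Construct a chromatogram tibble
#'
#' @param time Numeric vector of retention times (minutes), strictly increasing.
#' @param signal Numeric vector of detector responses (may be negative).
#' @param label Source identifier.
#' @return A tibble of class `chromatogram` with columns `time`, `signal`.
#' @export
chromatogram <- function(time, signal, label = "chromatogram") {
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal) || length(time) < 2L) {
    stop_xq("invalid_chromatogram", "time and signal must be equal length, >= 2")
  }
  if (any(diff(time) <= 0)) {
    stop_xq("nonmonotone_time", "retention times must be strictly increasing")
  }
  out <- tibble::tibble(time = time, signal = signal)
  attr(out, "label") <- label
  class(out) <- c("chromatogram", class(out))
  out
}

.quant_cols <- c("filename", "ion_name", "mz", "description", "retention_time",
                 "ms_intensity", "lc_intensity", "concentration")

#' Write quantification records as a long-format CSV
#'
#' One row per (file, ion) with the fixed column set `filename`, `ion_name`,
#' `mz`, `description`, `retention_time`, `ms_intensity`, `lc_intensity`,
#' `concentration`. Absent optional values are written as empty cells.
#' Output is RFC-4180-style CSV, UTF-8, LF line endings, header always present.
#'
#' @param records Tibble/data frame of quant records (see [quantify()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(records, path) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(.quant_cols, names(records))
  if (length(missing_cols)) {
    stop_xq("bad_schema", paste("records lack columns:", paste(missing_cols, collapse = ", ")))
  }
  out <- records[, .quant_cols]
  tryCatch(
    readr::write_csv(out, path, na = ""),
    error = function(e) stop_xq("unwritable_path", conditionMessage(e))
  )
  invisible(path)
}

#' Read a long-format quant CSV back into a tibble
#'
#' Inverse of [write_quant_csv()]; empty cells become `NA`.
#'
#' @param path CSV path.
#' @return Tibble with the standard quant columns.
#' @export
read_quant_csv <- function(path) {
  readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      filename = readr::col_character(),
      ion_name = readr::col_character(),
      mz = readr::col_double(),
      description = readr::col_character(),
      retention_time = readr::col_double(),
      ms_intensity = readr::col_double(),
      lc_intensity = readr::col_double(),
      concentration = readr::col_double()
    )
  )
}

#' Read a manual peak-label list
#'
#' For chromatography-only work: a delimited text file whose first column is a
#' peak name and whose next float column is its retention time (minutes).
#' Rows with a missing or non-numeric retention time are skipped with a
#' warning.
#'
#' @param path Path to the peak list.
#' @return Tibble with columns `name`, `retention_time`, `description`
#'   (file order preserved; zero rows for an empty file).
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) {
    stop_xq("unreachable_file", sprintf("cannot read peak list '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(name = character(), retention_time = numeric(),
                          description = character())
  if (!length(lines)) return(empty)
  # pick the first delimiter splitting the first row into >= 2 cells
  delim <- ","
  for (d in .delim_candidates) {
    if (length(.split_row(lines[[1]], d)) >= 2L) { delim <- d; break }
  }
  rows <- lapply(lines, function(line) {
    cells <- .split_row(line, delim)
    rt <- if (length(cells) >= 2L) suppressWarnings(as.numeric(cells[2])) else NA_real_
    if (is.na(rt) || rt < 0) return(NULL)
    tibble::tibble(name = cells[1], retention_time = rt,
                   description = if (length(cells) >= 3L) cells[3] else NA_character_)
  })
  n_bad <- sum(vapply(rows, is.null, logical(1)))
  if (n_bad > 0) {
    warning(sprintf("%d peak-list row(s) without a valid retention time skipped", n_bad),
            call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  dplyr::bind_rows(rows)
}
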