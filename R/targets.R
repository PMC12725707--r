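# Ion-target lists: the user's declaration of which compound ions to trace.

#' Read an ion-target list
#'
#' Two formats are accepted:
#' \itemize{
#'   \item JSON: an array of objects with fields `compound`, `mz` (scalar or
#'     array — one compound may declare several ions), optional `description`
#'     and `expected_rt`.
#'   \item Delimited text (same dialect candidates as chromatography files):
#'     columns `compound, mz[, description[, expected_rt]]`, one row per
#'     (compound, ion).
#' }
#'
#' @param path File path (`.json` selects the JSON reader).
#' @return Tibble with one row per (compound, ion): columns `compound`, `mz`,
#'   `description`, `expected_rt`.
#' @export
read_ion_targets <- function(path) {
  if (!file.exists(path)) {
    stop_xq("unreachable_file", sprintf("cannot read ion list '%s'", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    rows <- lapply(raw, function(x) {
      tibble::tibble(
        compound = x$compound,
        mz = as.numeric(unlist(x$mz)),
        description = if (is.null(x$description)) NA_character_ else x$description,
        expected_rt = if (is.null(x$expected_rt)) NA_real_ else as.numeric(x$expected_rt)
      )
    })
    out <- dplyr::bind_rows(rows)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(tibble::tibble(compound = character(), mz = numeric(),
                            description = character(), expected_rt = numeric()))
    }
    delim <- ","
    for (d in .delim_candidates) {
      if (length(.split_row(lines[[1]], d)) >= 2L) { delim <- d; break }
    }
    rows <- lapply(lines, function(line) {
      cells <- .split_row(line, delim)
      mzv <- if (length(cells) >= 2L) suppressWarnings(as.numeric(cells[2])) else NA_real_
      if (is.na(mzv)) return(NULL)  # header or malformed row
      tibble::tibble(
        compound = cells[1], mz = mzv,
        description = if (length(cells) >= 3L && nzchar(cells[3])) cells[3] else NA_character_,
        expected_rt = if (length(cells) >= 4L)
          suppressWarnings(as.numeric(cells[4])) else NA_real_
      )
    })
    out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  }
  if (nrow(out) == 0L || any(out$mz <= 0)) {
    stop_xq("bad_target", sprintf("'%s': no valid (compound, mz) rows", path))
  }
  out
}

# Ion display name: the compound name, disambiguated by m/z when a compound
# declares several ions.
.ion_names <- function(targets) {
  dplyr::group_by(targets, .data$compound) |>
    dplyr::mutate(ion_name = if (dplyr::n() == 1L) .data$compound
                  else sprintf("%s@%.4f", .data$compound, .data$mz)) |>
    dplyr::ungroup()
}
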