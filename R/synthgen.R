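# Deterministic synthetic data: chromatograms with drifting baselines,
# centroided MS1 runs with eluting target ions among random background ions,
# serial-dilution calibration series, and a minimal mzML writer. Every
# generator is a pure function of its arguments including the seed, and
# returns ground truth alongside the data so validation never has to
# re-derive expectations from generator internals.

#' Specify synthetic Gaussian peaks
#'
#' @param center_rt Peak apex retention times (minutes).
#' @param sigma Peak standard deviations (minutes).
#' @param amplitude Apex heights (counts / detector units).
#' @param mz Optional ion m/z for MS runs (Th).
#' @return Tibble with one row per peak.
#' @export
peak_spec <- function(center_rt, sigma, amplitude, mz = NA_real_) {
  stopifnot(all(sigma > 0), all(amplitude > 0))
  tibble::tibble(center_rt = center_rt, sigma = sigma,
                 amplitude = amplitude, mz = mz)
}

.time_axis <- function(duration, rate) {
  n <- round(duration * 60 * rate)
  list(n = n, t = (seq_len(n) - 1) / (rate * 60))  # minutes
}

#' Generate a synthetic chromatogram with known truth
#'
#' Signal = sum of Gaussian peaks + polynomial baseline + iid Gaussian noise,
#' sampled on a regular grid. Defaults emulate a routine LC acquisition:
#' a 15-minute run at 5 samples per second (4,500 samples).
#'
#' @param peaks A [peak_spec()] tibble (may have zero rows).
#' @param baseline Polynomial coefficients in ascending powers of time
#'   (minutes); `c(10, 2)` is the drifting line `10 + 2 t`.
#' @param noise_sigma Standard deviation of the additive noise (detector
#'   units).
#' @param duration Run length in minutes (default 15).
#' @param rate Sampling rate in samples per second (default 5).
#' @param seed Integer seed; identical arguments give identical output.
#' @return List with `chrom` (a [chromatogram()]) and `truth` (list: the peak
#'   table, `baseline` values, `clean` peaks-only signal, `noise_sigma`,
#'   `seed`).
#' @export
gen_chromatogram <- function(peaks = peak_spec(numeric(0), numeric(0), numeric(0)),
                             baseline = c(0), noise_sigma = 0,
                             duration = 15, rate = 5, seed = 1L) {
  stopifnot(duration > 0, rate > 0)
  ax <- .time_axis(duration, rate)
  t <- ax$t
  base <- rowSums(vapply(seq_along(baseline),
                         function(k) baseline[k] * t^(k - 1),
                         numeric(ax$n)))
  clean <- numeric(ax$n)
  for (p in seq_len(nrow(peaks))) {
    clean <- clean + peaks$amplitude[p] *
      exp(-(t - peaks$center_rt[p])^2 / (2 * peaks$sigma[p]^2))
  }
  noise <- if (noise_sigma > 0) {
    withr::with_seed(seed, stats::rnorm(ax$n, 0, noise_sigma))
  } else {
    numeric(ax$n)
  }
  chrom <- chromatogram(t, clean + base + noise, label = sprintf("synthetic-%d", seed))
  list(chrom = chrom,
       truth = list(peaks = peaks, baseline = base, clean = clean,
                    noise_sigma = noise_sigma, seed = seed))
}

#' Generate a synthetic centroided MS1 run with known truth
#'
#' Each scan carries the target compound ions — intensity following a
#' Gaussian elution profile evaluated at the scan's retention time, with
#' optional multiplicative noise — plus `background_ions` ions placed
#' uniformly over `mz_range` with exponentially distributed intensities
#' (roughly the dynamic range of real chemical noise). m/z arrays are sorted
#' ascending. The truth records, per scan, the exact intensity contributed by
#' each compound ion and the scan's total ion current.
#'
#' @param compounds [peak_spec()] tibble with an `mz` column.
#' @param background_ions Background ions per scan.
#' @param mz_range Length-2 numeric, low < high (Th).
#' @param noise_rel Relative (multiplicative) amplitude noise on compound
#'   ions.
#' @param bg_scale Mean of the exponential background intensities.
#' @param duration,rate,seed As in [gen_chromatogram()].
#' @return List with `run` (an `ms_run`) and `truth` (list: `compound_intensity`
#'   matrix scans x compounds, `tic` per scan, `times`, `peaks`, `seed`).
#' @export
gen_ms_run <- function(compounds, background_ions = 50,
                       mz_range = c(100, 1000), noise_rel = 0,
                       bg_scale = 100, duration = 2, rate = 1, seed = 1L) {
  stopifnot(length(mz_range) == 2L, mz_range[1] < mz_range[2])
  if (nrow(compounds) > 0) stopifnot(all(!is.na(compounds$mz)))
  ax <- .time_axis(duration, rate)
  t <- ax$t
  n_cmp <- nrow(compounds)
  withr::with_seed(seed, {
    cmp_int <- matrix(0, nrow = ax$n, ncol = max(n_cmp, 1L))
    scans_mz <- vector("list", ax$n)
    scans_in <- vector("list", ax$n)
    for (k in seq_len(ax$n)) {
      mzv <- numeric(0)
      inv <- numeric(0)
      for (p in seq_len(n_cmp)) {
        a <- compounds$amplitude[p] *
          exp(-(t[k] - compounds$center_rt[p])^2 / (2 * compounds$sigma[p]^2))
        if (noise_rel > 0) a <- a * (1 + stats::rnorm(1, 0, noise_rel))
        a <- max(a, 0)
        cmp_int[k, p] <- a
        mzv <- c(mzv, compounds$mz[p])
        inv <- c(inv, a)
      }
      if (background_ions > 0) {
        bmz <- stats::runif(background_ions, mz_range[1], mz_range[2])
        bin <- stats::rexp(background_ions, rate = 1 / bg_scale)
        mzv <- c(mzv, bmz)
        inv <- c(inv, bin)
      }
      o <- order(mzv)
      scans_mz[[k]] <- mzv[o]
      scans_in[[k]] <- inv[o]
    }
  })
  run <- tibble::tibble(
    index = seq_len(ax$n) - 1L, rt = t, ms_level = 1L,
    injection_time = NA_real_, mz = scans_mz, intensity = scans_in
  )
  run <- .as_ms_run(run, sprintf("synthetic-run-%d", seed))
  list(run = run,
       truth = list(compound_intensity = cmp_int[, seq_len(max(n_cmp, 1L)), drop = FALSE],
                    tic = vapply(scans_in, sum, numeric(1)),
                    times = t, peaks = compounds, seed = seed))
}

#' Build one dense high-resolution scan grid
#'
#' A single profile-like scan covering `mz_range` on a regular grid of the
#' given spacing — the worst-case array size a high-resolution instrument can
#' emit. A full scan of m/z 100–1000 at 0.001 Da spacing carries
#' `(1000 - 100) / 0.001 = 9e5` grid points per array, i.e. 1.8e6 values
#' across the m/z and intensity arrays together.
#'
#' @param mz_range Length-2 numeric (Th).
#' @param spacing Grid spacing / mass accuracy (Da).
#' @param intensity Constant intensity placed at every grid point.
#' @return List: `mz`, `intensity` (aligned vectors), `n_values` (total count
#'   across both arrays).
#' @export
gen_dense_scan <- function(mz_range = c(100, 1000), spacing = 0.001, intensity = 1) {
  n <- as.integer(round((mz_range[2] - mz_range[1]) / spacing))
  mz <- mz_range[1] + (seq_len(n) - 1) * spacing
  list(mz = mz, intensity = rep(intensity, n), n_values = 2L * n)
}

#' Write an MS run as minimal mzML
#'
#' Emits a schema-valid plain (non-indexed) mzML 1.1.0 document: run →
#' spectrumList → spectrum, each spectrum carrying its MS level, scan start
#' time in minutes, and uncompressed base64-encoded 64-bit float m/z and
#' intensity arrays. Intended for fixture generation and round-trip
#' validation against a full-featured reader; compression and 32-bit floats
#' are read-side capabilities only.
#'
#' @param run An `ms_run` tibble; an `ms_level` column above 1 is honoured
#'   (useful for exercising MS1 filtering on read).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  enc <- function(x) {
    # base64_enc wraps lines; mzML's encodedLength counts raw base64 only
    gsub("[\r\n]", "",
         jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                       endian = "little")))
  }
  n <- nrow(run)
  specs <- character(n)
  for (k in seq_len(n)) {
    mzb <- enc(run$mz[[k]])
    inb <- enc(run$intensity[[k]])
    specs[k] <- sprintf(
      paste0(
        '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
        '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
        '<scanList count="1">',
        '<cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
        '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.17g"',
        ' unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan>',
        '</scanList>',
        '<binaryDataArrayList count="2">',
        '<binaryDataArray encodedLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""',
        ' unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
        '<binary>%s</binary></binaryDataArray>',
        '<binaryDataArray encodedLength="%d">',
        '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
        '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""',
        ' unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
        '<binary>%s</binary></binaryDataArray>',
        '</binaryDataArrayList></spectrum>'
      ),
      k - 1L, k, length(run$mz[[k]]), as.integer(run$ms_level[k]), run$rt[k],
      nchar(mzb), mzb, nchar(inb), inb
    )
  }
  doc <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
      '<cvList count="2">',
      '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology"',
      ' URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
      '<cv id="UO" fullName="Unit Ontology"',
      ' URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
      '</cvList>\n',
      '<fileDescription><fileContent>',
      '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>',
      '</fileContent></fileDescription>\n',
      '<softwareList count="1"><software id="xicquant" version="0.1">',
      '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="xicquant"/>',
      '</software></softwareList>\n',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1">',
      '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
      '</instrumentConfiguration></instrumentConfigurationList>\n',
      '<dataProcessingList count="1"><dataProcessing id="dp1">',
      '<processingMethod order="1" softwareRef="xicquant">',
      '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
      '</processingMethod></dataProcessing></dataProcessingList>\n',
      '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
      '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n</spectrumList>\n',
      '</run>\n</mzML>'
    ),
    n, paste(specs, collapse = "\n")
  )
  ok <- tryCatch({ writeLines(doc, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_xq("unwritable_path", sprintf("cannot write mzML to '%s'", path))
  invisible(path)
}

#' Generate a serial-dilution calibration series with known truth
#'
#' One small MS1 run per concentration, written under a file name embedding
#' the concentration (the same token grammar
#' [impute_concentration_from_filename()] parses). The compound ion elutes as
#' a Gaussian whose amplitude is chosen so that the trapezoidal integral of
#' its elution profile equals `response_slope * concentration * (1 + eps)`
#' with `eps ~ N(0, noise_rel)` — a linear detector response with
#' multiplicative noise, the standard assumption behind serial-dilution
#' calibration.
#'
#' @param compound Compound name.
#' @param mz Ion m/z (Th).
#' @param concentrations Positive, distinct concentrations (default the
#'   five-point decade ladder 1, 10, 100, 1000, 10000).
#' @param response_slope True response per unit concentration.
#' @param noise_rel Relative noise on the realised response.
#' @param unit Concentration unit embedded in the file names.
#' @param dir Directory in which to write the mzML files.
#' @param duration,rate Acquisition grid of each run (default 2 min at
#'   1 scan/s).
#' @param background_ions Background ions per scan.
#' @param seed Integer seed.
#' @param write_files Write each run as mzML under `dir` (default). With
#'   `FALSE` the runs are returned in memory only (`path` is `NA`).
#' @return List with `files` (tibble: `filename`, `path`, `concentration`,
#'   `true_response`), `runs` (list of `ms_run` objects, parallel to `files`)
#'   and `truth` (list incl. `compound`, `mz`, `response_slope`, `seed`).
#' @export
gen_calibration_series <- function(compound = "analyte", mz = 180.0634,
                                   concentrations = c(1, 10, 100, 1000, 10000),
                                   response_slope = 12, noise_rel = 0.01,
                                   unit = "uM", dir = tempdir(),
                                   duration = 2, rate = 1,
                                   background_ions = 20, seed = 1L,
                                   write_files = TRUE) {
  stopifnot(all(concentrations > 0), !anyDuplicated(concentrations))
  center <- duration / 2
  sigma <- duration / 12
  eps <- withr::with_seed(seed, stats::rnorm(length(concentrations), 0, noise_rel))
  rows <- vector("list", length(concentrations))
  runs <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    conc <- concentrations[i]
    true_resp <- response_slope * conc * (1 + eps[i])
    amp <- true_resp / (sigma * sqrt(2 * pi))
    g <- gen_ms_run(
      peak_spec(center_rt = center, sigma = sigma, amplitude = amp, mz = mz),
      background_ions = background_ions, mz_range = c(50, 500),
      duration = duration, rate = rate, seed = seed * 1000L + i
    )
    fname <- sprintf("cal_%s%s_s%d.mzML", format(conc, scientific = FALSE),
                     unit, seed)
    # one file per concentration point; replicate index keeps names unique
    fname <- sub("\\.mzML$", sprintf("_p%d.mzML", i), fname)
    fpath <- NA_character_
    if (write_files) {
      fpath <- file.path(dir, fname)
      write_mzml(g$run, fpath)
    }
    runs[[i]] <- g$run
    rows[[i]] <- tibble::tibble(filename = fname, path = fpath,
                                concentration = conc, true_response = true_resp)
  }
  files <- dplyr::bind_rows(rows)
  list(files = files, runs = runs,
       truth = list(compound = compound, mz = mz,
                    response_slope = response_slope, noise_rel = noise_rel,
                    center_rt = center, sigma = sigma, unit = unit, seed = seed))
}
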