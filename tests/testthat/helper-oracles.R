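# Shared oracles and fixtures, built in code at test time.

# Naive full-scan reference for XIC extraction: linear scan of every m/z
# value per (window, scan), independent of the binary-search implementation.
naive_xic <- function(run, windows) {
  out <- matrix(0, nrow = nrow(run), ncol = nrow(windows))
  for (w in seq_len(nrow(windows))) {
    for (k in seq_len(nrow(run))) {
      mz <- run$mz[[k]]
      keep <- mz >= windows$low[w] & mz <= windows$high[w]
      out[k, w] <- sum(run$intensity[[k]][keep])
    }
  }
  out
}

random_run <- function(seed, max_scans = 60, max_points = 400) {
  withr::with_seed(seed, {
    n_scans <- sample(2:max_scans, 1)
    scans_mz <- vector("list", n_scans)
    scans_in <- vector("list", n_scans)
    for (k in seq_len(n_scans)) {
      m <- sample(0:max_points, 1)
      scans_mz[[k]] <- sort(stats::runif(m, 50, 1200))
      scans_in[[k]] <- stats::rexp(m, 1 / 100)
    }
    run <- tibble::tibble(
      index = seq_len(n_scans) - 1L, rt = (seq_len(n_scans) - 1) / 60,
      ms_level = 1L, injection_time = NA_real_,
      mz = scans_mz, intensity = scans_in
    )
    xicquant:::.as_ms_run(run, sprintf("rand-%d", seed))
  })
}

random_windows <- function(seed, max_windows = 20) {
  withr::with_seed(seed + 5000, {
    n <- sample(1:max_windows, 1)
    centers <- stats::runif(n, 60, 1100)
    tibble::tibble(
      window_id = seq_len(n), center = centers,
      low = centers - stats::runif(n, 1e-4, 2),
      high = centers + stats::runif(n, 1e-4, 2),
      owners = replicate(n, tibble::tibble(compound = "c", mz = 1), simplify = FALSE)
    )
  })
}

# A small on-disk study: ion list + three synthetic mzML samples.
make_study <- function(dir, seed = 1L) {
  ions <- file.path(dir, "ions.csv")
  writeLines(c("glucose,180.0634,hexose,1.0",
               "citrate,191.0197,,1.0"), ions)
  mzmls <- character(3)
  for (i in 1:3) {
    g <- gen_ms_run(
      peak_spec(c(1.0, 1.0), c(0.15, 0.15), c(5000 * i, 3000 * i),
                mz = c(180.0634, 191.0197)),
      background_ions = 20, mz_range = c(100, 400),
      duration = 2, rate = 1, seed = seed * 100L + i
    )
    mzmls[i] <- file.path(dir, sprintf("sample%d.mzML", i))
    write_mzml(g$run, mzmls[i])
  }
  list(ions = ions, mzmls = mzmls)
}
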