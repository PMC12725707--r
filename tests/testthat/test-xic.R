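test_that("windows deduplicate identical ions and apply ppm/dalton half-widths", {
  targets <- tibble::tibble(
    compound = c("glucose", "fructose", "citrate"),
    mz = c(180.0634, 180.0634, 191.0197)
  )
  w <- build_windows(targets, mass_tol(ppm = 3))
  expect_equal(nrow(w), 2L)  # the shared hexose ion collapses to one window
  hex <- w[abs(w$center - 180.0634) < 1e-9, ]
  expect_equal(nrow(hex$owners[[1]]), 2L)
  expect_setequal(hex$owners[[1]]$compound, c("glucose", "fructose"))

  # 3 ppm at m/z 500 is a 0.0015 Th half-width
  w500 <- build_windows(tibble::tibble(compound = "x", mz = 500), mass_tol(ppm = 3))
  expect_equal(w500$high - w500$center, 500 * 3e-6)
  expect_equal(w500$center - w500$low, 500 * 3e-6)

  # +/- 0.0003 Da around 147.0764
  wda <- build_windows(tibble::tibble(compound = "x", mz = 147.0764),
                       mass_tol(da = 0.0003))
  expect_equal(wda$low, 147.0761)
  expect_equal(wda$high, 147.0767)

  # U <= C x I under random duplication
  withr::with_seed(8, {
    tg <- tibble::tibble(
      compound = sample(letters[1:5], 30, TRUE),
      mz = sample(c(100.1, 200.2, 300.3, 400.4), 30, TRUE)
    )
  })
  expect_lte(nrow(build_windows(tg)), nrow(tg))
})

test_that("scan_window_intensity matches a linear scan, closed on both ends", {
  mz <- c(100, 200, 300)
  inten <- c(1, 2, 3)
  expect_equal(scan_window_intensity(mz, inten, 199.9, 200.1), 2)
  expect_equal(scan_window_intensity(numeric(0), numeric(0), 1, 2), 0)
  expect_equal(scan_window_intensity(mz, inten, 0, 1000), sum(inten))
  # boundary ties included on both sides
  expect_equal(scan_window_intensity(mz, inten, 200, 300), 5)
  expect_equal(scan_window_intensity(mz, inten, 100, 200), 3)
  expect_equal(scan_window_intensity(mz, inten, 300.0001, 400), 0)
})

test_that("optimized extraction equals the naive oracle exactly on random runs", {
  for (seed in 1:15) {
    run <- random_run(seed)
    windows <- random_windows(seed)
    got <- extract_xics(run, windows)
    want <- naive_xic(run, windows)
    for (w in seq_len(nrow(windows))) {
      expect_identical(got$intensity[got$window_id == w], want[, w])
    }
    expect_equal(unique(got$time), run$rt)
  }
})

test_that("grouped windows fan out to identical per-(compound, ion) traces", {
  targets <- tibble::tibble(
    compound = c("a", "b", "c"),
    mz = c(180.0634, 180.0634, 250.5)
  )
  g <- gen_ms_run(peak_spec(c(1, 1.5), c(0.2, 0.2), c(1000, 800),
                            mz = c(180.0634, 250.5)),
                  background_ions = 50, duration = 2, rate = 1, seed = 4)
  grouped <- extract_xics(g$run, build_windows(targets))
  # ungrouped: one window per declared row, no dedup
  per_row <- lapply(seq_len(nrow(targets)), function(i)
    build_windows(targets[i, ]))
  for (i in seq_len(nrow(targets))) {
    ug <- extract_xics(g$run, per_row[[i]])
    ctr <- round(targets$mz[i], 6)
    expect_identical(ug$intensity,
                     grouped$intensity[abs(grouped$center - ctr) < 1e-9])
  }
})

test_that("disjoint windows covering the full m/z range sum to the TIC", {
  g <- gen_ms_run(peak_spec(1, 0.3, 500, mz = 300), background_ions = 100,
                  mz_range = c(100, 1000), duration = 1, rate = 1, seed = 6)
  cut <- 400
  windows <- tibble::tibble(
    window_id = 1:2, center = c(250, 700),
    low = c(0, cut + 1e-9), high = c(cut, 2000),
    owners = list(tibble::tibble(compound = "l", mz = 1),
                  tibble::tibble(compound = "r", mz = 2))
  )
  tr <- extract_xics(g$run, windows)
  summed <- tr |> dplyr::group_by(time) |> dplyr::summarise(s = sum(intensity))
  expect_equal(summed$s, g$truth$tic)
})

test_that("XIC apex lands within one scan interval of the true elution apex", {
  g <- gen_ms_run(peak_spec(1.0, 0.15, 2000, mz = 400.2), background_ions = 30,
                  duration = 2, rate = 2, seed = 12)
  w <- build_windows(tibble::tibble(compound = "x", mz = 400.2))
  tr <- extract_xics(g$run, w)
  apex_t <- tr$time[which.max(tr$intensity)]
  scan_dt <- diff(g$truth$times[1:2])
  expect_lte(abs(apex_t - 1.0), scan_dt)
})

test_that("annotation matches apexes to nearest labels with earlier-RT tie-break", {
  g <- gen_ms_run(peak_spec(1.0, 0.1, 1000, mz = 222.2), background_ions = 0,
                  duration = 2, rate = 2, seed = 3)
  w <- build_windows(tibble::tibble(compound = "x", mz = 222.2))
  tr <- extract_xics(g$run, w)

  labels <- tibble::tibble(name = "pk", retention_time = 1.05)
  ann <- annotate_with_chromatography(tr, labels = labels, rt_tol = 0.5)
  expect_true(ann$matched)
  expect_equal(ann$label_name, "pk")

  far <- tibble::tibble(name = "far", retention_time = 9)
  ann2 <- annotate_with_chromatography(tr, labels = far, rt_tol = 0.5)
  expect_false(ann2$matched)

  # two labels equidistant from the apex: the earlier retention time wins
  apex_t <- ann$apex_time
  ties <- tibble::tibble(name = c("late", "early"),
                         retention_time = c(apex_t + 0.2, apex_t - 0.2))
  ann3 <- annotate_with_chromatography(tr, labels = ties, rt_tol = 0.5)
  expect_equal(ann3$label_name, "early")
})
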