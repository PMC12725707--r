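test_that("filename imputation parses the first number+unit token", {
  expect_equal(as.numeric(impute_concentration_from_filename("std_100uM_r1.mzML")), 100)
  expect_equal(attr(impute_concentration_from_filename("std_100uM_r1.mzML"), "unit"), "uM")
  expect_true(is.na(impute_concentration_from_filename("blank.mzML")))
  expect_equal(as.numeric(impute_concentration_from_filename("cal-2.5mM-a.mzML")), 2.5)
  expect_equal(attr(impute_concentration_from_filename("cal-2.5mM-a.mzML"), "unit"), "mM")
  expect_equal(as.numeric(impute_concentration_from_filename("x_10ng/ml.mzML")), 10)
  # unit token must not run into more letters, and the extension is not a unit
  expect_true(is.na(impute_concentration_from_filename("sample_2Methyl.mzML")))
  expect_equal(as.numeric(impute_concentration_from_filename("a_1uM_b_7mM.mzML")), 1)
})

test_that("OLS calibration matches the closed form and recovers exact fits", {
  # closed-form OLS oracle
  ols <- function(x, y) {
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    c(slope = sl, intercept = mean(y) - sl * mean(x))
  }
  pts <- tibble::tibble(concentration = c(1, 10, 100), response = c(10, 100, 1000))
  cv <- fit_calibration(pts, "linear")
  want <- ols(pts$concentration, pts$response)
  expect_equal(cv$slope, unname(want["slope"]))
  expect_equal(cv$intercept, unname(want["intercept"]))
  expect_equal(cv$r_squared, 1)

  # same decade ladder on the log-log scale is the exact power law y = 10 x
  cvl <- fit_calibration(pts, "loglog")
  expect_equal(cvl$slope, 1)
  expect_equal(cvl$intercept, 1)
  expect_equal(cvl$r_squared, 1)

  # noiseless y = 5x + 2 at 5 points
  x5 <- c(1, 2, 3, 4, 5)
  cv5 <- fit_calibration(tibble::tibble(concentration = x5, response = 5 * x5 + 2))
  expect_equal(cv5$slope, 5)
  expect_equal(cv5$intercept, 2)
  expect_equal(cv5$r_squared, 1)

  # a noisy design agrees with the closed form too
  withr::with_seed(77, {
    x <- stats::runif(8, 1, 50)
    y <- 3 * x + 4 + stats::rnorm(8)
  })
  cvn <- fit_calibration(tibble::tibble(concentration = x, response = y))
  wn <- ols(x, y)
  expect_equal(cvn$slope, unname(wn["slope"]))
  expect_equal(cvn$intercept, unname(wn["intercept"]))

  expect_error(fit_calibration(tibble::tibble(concentration = c(2, 2),
                                              response = c(1, 2))),
               class = "xq_degenerate_design")
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 2),
                                              response = c(-1, 2)), "loglog"),
               class = "xq_nonpositive_value")
})

test_that("tidy() and glance() expose the fit in broom style", {
  pts <- tibble::tibble(concentration = c(1, 10, 100, 1000),
                        response = c(12, 110, 980, 10500))
  cv <- fit_calibration(pts, compound = "glucose")
  td <- tidy(cv)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate, c(cv$intercept, cv$slope))
  gl <- glance(cv)
  expect_equal(gl$compound, "glucose")
  expect_equal(gl$n_points, 4L)
})

test_that("concentration estimation inverts the curve and flags extrapolation", {
  lin <- structure(list(slope = 10, intercept = 0, scale = "linear",
                        points = tibble::tibble(concentration = c(1, 100))),
                   class = "calibration_curve")
  expect_equal(as.numeric(estimate_concentration(lin, 500)), 50)
  expect_false(attr(estimate_concentration(lin, 500), "extrapolated"))
  expect_true(attr(estimate_concentration(lin, 5000), "extrapolated"))

  ll <- structure(list(slope = 1, intercept = 1, scale = "loglog",
                       points = tibble::tibble(concentration = c(1, 1000))),
                  class = "calibration_curve")
  expect_equal(as.numeric(estimate_concentration(ll, 1000)), 100)
  zero <- structure(list(slope = 0, intercept = 0, scale = "linear",
                         points = tibble::tibble(concentration = c(1, 2))),
                    class = "calibration_curve")
  expect_error(estimate_concentration(zero, 1), class = "xq_zero_slope")
})

test_that("fit-then-invert is the identity on a noiseless linear model", {
  x <- c(1, 5, 10, 50, 100)
  cv <- fit_calibration(tibble::tibble(concentration = x, response = 12 * x + 3))
  for (c0 in c(2, 20, 80)) {
    expect_equal(as.numeric(estimate_concentration(cv, 12 * c0 + 3)), c0,
                 tolerance = 1e-9)
  }
})

test_that("R^2 decreases as injected noise grows (expectation over seeds)", {
  mean_r2 <- function(noise) {
    r2 <- vapply(1:100, function(s) {
      withr::with_seed(s, {
        x <- c(1, 10, 100, 1000, 10000)
        y <- 7 * x * (1 + stats::rnorm(5, 0, noise))
      })
      fit_calibration(tibble::tibble(concentration = x, response = y))$r_squared
    }, numeric(1))
    mean(r2)
  }
  r <- vapply(c(0.01, 0.2, 0.8), mean_r2, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("quantify fills unknowns, echoes calibrants, isolates failures", {
  mk_results <- function(files, compound, resp) {
    tibble::tibble(
      filename = files, compound = compound, ion_name = compound,
      mz = 100.5, description = NA_character_, retention_time = 1,
      ms_intensity = resp, lc_intensity = NA_real_
    )
  }
  cal_files <- sprintf("cal_%duM.mzML", c(1, 10, 100, 1000, 10000))
  files <- c(cal_files, "unknownA.mzML", "unknownB.mzML")
  resp <- 20 * c(1, 10, 100, 1000, 10000, 55, 700)
  results <- mk_results(files, "glucose", resp)

  q <- quantify(results, calibration = "from-filename")
  expect_equal(nrow(q$records), 7L)
  est <- q$records$concentration[q$records$filename == "unknownA.mzML"]
  expect_equal(est, 55, tolerance = 1e-6)
  # calibrant rows echo the known value, never a re-estimate
  expect_equal(
    q$records$concentration[q$records$filename %in% cal_files],
    c(1, 10, 100, 1000, 10000)
  )

  # a compound with a degenerate design is isolated; others unaffected
  bad <- mk_results(c("cal_5uM_x.mzML", "cal_5uM_y.mzML", "unknownC.mzML"),
                    "broken", c(10, 11, 12))
  both <- dplyr::bind_rows(results, bad)
  expect_warning(q2 <- quantify(both), "broken")
  expect_true(all(is.na(
    q2$records$concentration[q2$records$ion_name == "broken" &
                             q2$records$filename == "unknownC.mzML"])))
  expect_equal(
    q2$records$concentration[q2$records$filename == "unknownA.mzML"], 55,
    tolerance = 1e-6
  )
})

test_that("one concentration per file is enforced", {
  results <- tibble::tibble(
    filename = "a.mzML", compound = "x", ion_name = "x", mz = 1,
    description = NA_character_, retention_time = 1,
    ms_intensity = 10, lc_intensity = NA_real_
  )
  mapping <- tibble::tibble(filename = c("a.mzML", "a.mzML"),
                            concentration = c(1, 2))
  expect_error(quantify(results, calibration = mapping),
               class = "xq_multiple_concentrations")
  expect_error(
    quantify(results, calibration = tibble::tibble(filename = "ghost.mzML",
                                                   concentration = 1)),
    class = "xq_missing_calibrant"
  )
})

test_that("synthetic series recovers the 100-unit point within 5%", {
  errs <- vapply(1:25, function(s) {
    g <- gen_calibration_series(noise_rel = 0.01, seed = s,
                                background_ions = 0, dir = withr::local_tempdir())
    # integrated response per file from the written mzML, through the XIC path
    w <- build_windows(tibble::tibble(compound = "analyte", mz = g$truth$mz))
    resp <- vapply(g$files$path, function(p) {
      tr <- extract_xics(read_ms_run(p), w)
      integrate_total(tr$time, tr$intensity)
    }, numeric(1))
    cv <- fit_calibration(tibble::tibble(concentration = g$files$concentration,
                                         response = unname(resp)))
    est <- as.numeric(estimate_concentration(cv, resp[g$files$concentration == 100]))
    abs(est - 100) / 100
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})
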