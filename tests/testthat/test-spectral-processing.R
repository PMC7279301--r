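test_that("flat spectrum with equal endpoints gives a constant background", {
  spec <- xps_spectrum(seq(282, 292, 0.05), rep(40, 201))
  res <- shirley_background(spec)
  expect_true(res$converged)
  expect_equal(res$background$intensity, rep(40, 201))
  expect_equal(res$corrected$intensity, rep(0, 201))
})

test_that("an isolated peak on zero baseline needs no background", {
  spec <- gaussian_spectrum(center = 287, fwhm = 1.1, height = 1000)
  res <- shirley_background(spec, 282, 292)
  expect_true(res$converged)
  expect_lt(max(abs(res$background$intensity)), 1e-3 * 1000)
})

test_that("a forward-constructed Shirley step is recovered", {
  peak <- gaussian_spectrum(center = 286, fwhm = 1.3, height = 5000,
                            grid = seq(281, 291, 0.02))
  fx <- shirley_fixture(peak, b_lo = 200, b_hi = 1400)
  res <- shirley_background(fx$spectrum, 281, 291)
  expect_true(res$converged)
  rms <- sqrt(mean((res$background$intensity - fx$background)^2))
  expect_lt(rms, 0.005 * 5000)                       # within 0.5% of the peak
  # background monotone between its endpoints for a single peak
  expect_true(all(diff(res$background$intensity) >= -1e-9))
  # corrected signal recovers the pure peak
  expect_lt(max(abs(res$corrected$intensity - peak$intensity)), 0.005 * 5000)
})

test_that("non-convergence is flagged, never silent", {
  # unequal endpoints force real iteration (equal ones converge in one step)
  fx <- shirley_fixture(gaussian_spectrum(height = 1000), b_lo = 50,
                        b_hi = 400)
  res <- shirley_background(fx$spectrum, tol = 1e-15, max_iter = 2L)
  expect_false(res$converged)
  expect_true(any(grepl("not-converged", res$corrected$provenance)))
  expect_lte(res$iterations_used, 2L)
})

test_that("Shirley window validation", {
  spec <- gaussian_spectrum()
  expect_error(shirley_background(spec, 290, 284), "below")
  expect_error(shirley_background(spec, 200, 292), "inside")
})

test_that("calibration shifts the apex onto the reference energy", {
  spec <- gaussian_spectrum(center = 285.6)
  cal <- calibrate_energy(spec)
  apex <- cal$energy[which.max(cal$intensity)]
  expect_equal(apex, 285.0, tolerance = 0.006)
  expect_true(any(grepl("-0.6000", cal$provenance)))
  # idempotence: calibrating again shifts by < grid-step/10
  cal2 <- calibrate_energy(cal)
  expect_lt(max(abs(cal2$energy - cal$energy)), 0.05 / 10)
})

test_that("calibration round-trips a rigid shift", {
  # apex deliberately off-grid so sub-channel interpolation is exercised
  spec <- gaussian_spectrum(center = 285.013)
  shifted <- xps_spectrum(spec$energy + 0.3, spec$intensity)
  back <- calibrate_energy(shifted, reference_be = 285.013)
  expect_lt(max(abs(back$energy - spec$energy)), 0.005)
  expect_error(calibrate_energy(xps_spectrum(1:10, rep(2, 10))), "flat")
})

test_that("resampling and normalization behave as exact linear operations", {
  spec <- gaussian_spectrum()
  expect_equal(resample(spec, spec$energy)$intensity, spec$intensity)
  ramp <- xps_spectrum(seq(280, 290, 1), 2 * seq(280, 290, 1) - 400)
  sub <- seq(280.5, 289.5, 0.25)
  expect_equal(resample(ramp, sub)$intensity, 2 * sub - 400)
  expect_error(resample(spec, seq(270, 280, 1)), "extrapolate")
  n1 <- normalize_max(spec)
  expect_equal(max(n1$intensity), 1)
  expect_identical(normalize_max(n1)$intensity, n1$intensity)
  expect_error(normalize_max(xps_spectrum(1:5, rep(0, 5))), "not positive")
})

test_that("provenance records processing steps in order", {
  spec <- gaussian_spectrum(height = 1000, baseline = 20)
  out <- normalize_max(shirley_background(spec)$corrected)
  i_sh <- grep("shirley", out$provenance)[1]
  i_no <- grep("max-normalized", out$provenance)[1]
  expect_lt(i_sh, i_no)
})

test_that("spectrum CSV I/O round-trips and tolerates XPS display order", {
  spec <- gaussian_spectrum(height = 123.4)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(spec, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$energy, spec$energy)
  expect_equal(back$intensity, spec$intensity)
  # descending-BE file (display convention) is re-sorted ascending
  desc <- tempfile(fileext = ".csv")
  writeLines(c("# comment", paste(rev(spec$energy), rev(spec$intensity),
                                  sep = ",")), desc)
  back2 <- read_spectrum_csv(desc)
  expect_equal(back2$energy, spec$energy)
  expect_equal(back2$intensity, spec$intensity)
})

test_that("CasaXPS-style tab-separated exports are readable", {
  spec <- gaussian_spectrum()
  path <- tempfile(fileext = ".txt")
  writeLines(c("B.E.\tCPS\tComment",
               paste(spec$energy, spec$intensity, "x", sep = "\t")), path)
  back <- read_casaxps(path)
  expect_equal(back$energy, spec$energy)
  expect_equal(back$intensity, spec$intensity, tolerance = 1e-12)
})

test_that("spectrum container enforces its invariants", {
  expect_error(xps_spectrum(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(xps_spectrum(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
  expect_error(xps_spectrum(c(1, NA, 2), c(1, 2, 3)), "non-finite|same length")
  neg <- xps_spectrum(1:5, c(1, -0.1, 2, 3, 1))
  expect_true(any(grepl("negative", neg$provenance)))
})
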