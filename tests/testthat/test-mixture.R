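sub_spec <- simulate_protein_spectrum(pcl_theoretical_profile())
apo_spec <- simulate_protein_spectrum(
  composition_profile(protein_fixture("apoa1")))

test_that("mixing is the identity at its endpoints and a fixed point", {
  expect_equal(mix_spectra(sub_spec, apo_spec, 0)$intensity,
               sub_spec$intensity)
  expect_equal(mix_spectra(sub_spec, apo_spec, 1)$intensity,
               apo_spec$intensity)
  for (x in c(0.2, 0.7))
    expect_equal(mix_spectra(sub_spec, sub_spec, x)$intensity,
                 sub_spec$intensity)
  expect_error(mix_spectra(sub_spec, apo_spec, 1.2), "\\[0, 1\\]")
  expect_error(mix_spectra(sub_spec, apo_spec, -0.1), "\\[0, 1\\]")
  other <- xps_spectrum(seq(283, 291, 0.1), rep(1, 81))
  expect_error(mix_spectra(sub_spec, other, 0.5), "grid")
})

test_that("noiseless mixtures are recovered exactly at the scan resolution", {
  for (x_true in c(0, 0.09, 0.5)) {
    measured <- mix_spectra(sub_spec, apo_spec, x_true)
    fit <- fit_coverage(sub_spec, apo_spec, measured)
    expect_lt(abs(fit$x_hat - x_true), 0.0025)
    expect_lt(fit$fit_quality$rmse, 1e-8)
  }
  # measured identical to the substrate -> no protein
  fit0 <- fit_coverage(sub_spec, apo_spec, sub_spec)
  expect_lt(fit0$x_hat, 0.0025)
})

test_that("the refined optimum matches an exhaustive fine-grid oracle", {
  set.seed(7)
  measured <- mix_spectra(sub_spec, apo_spec, 0.13)
  counts <- rpois(length(measured$intensity),
                  measured$intensity / max(measured$intensity) * 1e4)
  noisy <- xps_spectrum(measured$energy, counts)
  fit <- fit_coverage(sub_spec, apo_spec, noisy)
  expect_lt(abs(fit$x_hat - 0.13), 0.01)

  # independent brute force: direct RMSE at step 1e-4, no fit_coverage code
  s <- sub_spec$intensity; p <- apo_spec$intensity
  m <- counts / max(counts)
  xs <- seq(0, 1, by = 1e-4)
  rmse <- vapply(xs, function(x) {
    mod <- (1 - x) * s + x * p
    mod <- mod / max(mod)
    sqrt(mean((mod - m)^2))
  }, 0)
  expect_lt(abs(fit$x_hat - xs[which.min(rmse)]), 5e-4)
  # the coarse scan can never undercut the exhaustive fine-grid minimum
  expect_gte(min(fit$objective_curve$objective),
             rmse[which.min(rmse)] - 1e-12)
})

test_that("coverage is invariant to the measured spectrum's scale", {
  measured <- mix_spectra(sub_spec, apo_spec, 0.11)
  scaled <- xps_spectrum(measured$energy, 7.3 * measured$intensity)
  f1 <- fit_coverage(sub_spec, apo_spec, measured)
  f2 <- fit_coverage(sub_spec, apo_spec, scaled)
  expect_equal(f1$x_hat, f2$x_hat, tolerance = 1e-10)
})

test_that("objective at the truth is the global scan minimum (noiseless)", {
  for (x_true in c(0.05, 0.13, 0.35)) {
    measured <- mix_spectra(sub_spec, apo_spec, x_true)
    fit <- fit_coverage(sub_spec, apo_spec, measured, x_grid_step = 0.005)
    k <- which.min(fit$objective_curve$objective)
    expect_equal(fit$objective_curve$x[k], x_true, tolerance = 0.005)
    expect_false(fit$weakly_identified)
  }
})

test_that("substrate distortion degrades the attainable fit quality", {
  measured <- mix_spectra(sub_spec, apo_spec, 0.15)
  clean <- fit_coverage(sub_spec, apo_spec, measured)
  # emulate an extra ether-region (286.5 eV) feature in the real substrate
  distort <- gaussian_spectrum(center = 286.5, fwhm = 1.1, height = 0.25,
                               grid = sub_spec$energy)
  sub_d <- normalize_max(xps_spectrum(sub_spec$energy,
                                      sub_spec$intensity + distort$intensity))
  degraded <- fit_coverage(sub_d, apo_spec, measured)
  expect_gt(degraded$fit_quality$rmse, clean$fit_quality$rmse + 1e-4)
  expect_lt(degraded$fit_quality$r_squared, clean$fit_quality$r_squared)
})

test_that("indistinguishable components are flagged as weakly identified", {
  fit <- fit_coverage(sub_spec, sub_spec, sub_spec)
  expect_true(fit$weakly_identified)
})

test_that("joint rigid-shift search absorbs a miscalibrated measured grid", {
  measured <- mix_spectra(sub_spec, apo_spec, 0.13)
  off <- xps_spectrum(measured$energy + 0.3, measured$intensity)
  plain <- fit_coverage(sub_spec, apo_spec, off)
  shifted <- fit_coverage(sub_spec, apo_spec, off, shift_search = 0.5)
  expect_gt(abs(plain$x_hat - 0.13), abs(shifted$x_hat - 0.13))
  expect_lt(abs(shifted$x_hat - 0.13), 0.005)
  expect_equal(shifted$energy_shift, -0.3, tolerance = 0.02)
})

test_that("coverage_fit behaves like a fitted-model object", {
  measured <- mix_spectra(sub_spec, apo_spec, 0.09)
  fit <- fit_coverage(sub_spec, apo_spec, measured)
  expect_s3_class(fit, "coverage_fit")
  expect_equal(unname(coef(fit)), fit$x_hat)
  expect_equal(fitted(fit), predict(fit)$intensity)
  expect_equal(residuals(fit),
               fit$spectra$measured$intensity - fitted(fit))
  expect_identical(fit$percent, 9L)
  expect_output(print(fit), "coverage x = 0.0900")
  expect_output(print(summary(fit)), "max \\|residual\\|")
  two <- predict(fit, x = c(0.1, 0.2))
  expect_length(two, 2)
  sims <- simulate(fit, nsim = 2, seed = 1, peak_counts = 500)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$intensity >= 0))
  sims_again <- simulate(fit, nsim = 2, seed = 1, peak_counts = 500)
  expect_identical(sims[[1]]$intensity, sims_again[[1]]$intensity)
})

test_that("relative coverage increase follows the percent-change formula", {
  inc <- coverage_increase(0.09, 0.13)
  expect_equal(inc$value, 100 * 4 / 9)
  expect_identical(inc$percent, 44L)
  expect_equal(coverage_increase(0.08, 0.15)$value, 87.5)
  expect_equal(coverage_increase(0.2, 0.2)$value, 0)
  expect_error(coverage_increase(0, 0.1), "> 0")
})
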