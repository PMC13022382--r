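test_that("dye-corrected protein concentration follows the correction formula", {
  # SiR-labeled sample: (0.5 - 1.0 * 0.147) / 40000 = 8.825e-6 M
  expect_equal(corrected_concentration(0.5, 1.0, "SiR", 40000), 8.825e-6)
  expect_equal(corrected_concentration(0.5, 1.0, 0.147, 40000), 8.825e-6)
  # built-in dye table carries the TMR value 0.34
  expect_equal(corrected_concentration(1, 1, "TMR", 1e5),
               (1 - 0.34) / 1e5)
  # unlabeled protein: plain A280 / eps * dilution
  expect_equal(corrected_concentration(0.8, 0, "TMR", 40000, dilution = 5),
               0.8 / 40000 * 5)
  # linear in dilution, decreasing in CF
  c1 <- corrected_concentration(0.5, 1, 0.1, 4e4, dilution = 2)
  expect_equal(c1, 2 * corrected_concentration(0.5, 1, 0.1, 4e4))
  expect_lt(corrected_concentration(0.5, 1, 0.2, 4e4), c1 / 2 + c1)
  expect_error(corrected_concentration(0.1, 1, "TMR", 4e4), "negative")
  # extensible dye table
  expect_equal(corrected_concentration(0.5, 1, "CPY", 4e4,
                                       extra = c(CPY = 0.2)),
               (0.5 - 0.2) / 4e4)
})

test_that("Lambert-Beer concentrations scale as expected", {
  expect_equal(beer_lambert_concentration(0, 1e5), 0)
  expect_equal(beer_lambert_concentration(1, 1e5, 1), 1e-5)
  expect_equal(beer_lambert_concentration(1, 1e5, 2),
               beer_lambert_concentration(1, 1e5, 1) / 2)
})

test_that("turn_on_fold compares emission scans consistently", {
  wl <- seq(600, 700, 5)
  base <- 100 + 900 * exp(-((wl - 660) / 18)^2)
  mk <- function(y, reps = 1) {
    assay_table(do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(series = paste0("r", r), wavelength = wl, intensity = y)
    })), "emission_scan")
  }
  expect_equal(turn_on_fold(mk(base), mk(base)), 1.0)
  expect_equal(turn_on_fold(mk(6.2 * base), mk(base)), 6.2)
  expect_equal(turn_on_fold(mk(6.2 * base), mk(base), mode = "integral"), 6.2)
  # replicates are averaged before the ratio
  expect_equal(turn_on_fold(mk(3 * base, reps = 3), mk(base)), 3)
  expect_error(turn_on_fold(mk(0 * base), mk(0 * base)), "zero")
  wl2 <- wl + 2.5
  tab2 <- assay_table(data.frame(series = "r1", wavelength = wl2,
                                 intensity = base), "emission_scan")
  expect_error(turn_on_fold(mk(base), tab2), "grid")
})

test_that("melting_temperature finds the derivative maximum of the transition", {
  # noiseless sigmoid with inflection at 46.3 degC
  curve <- sim_melt_curve(study$mT, noise = noise_spec(replicates = 2))
  fit <- melting_temperature(curve)
  expect_false(fit$no_transition)
  expect_equal(fit$mT, study$mT, tolerance = 0.1 / study$mT)

  # affine rescaling of the ratio axis does not move the inflection
  scaled <- curve
  scaled$ratio <- 5 + 40 * scaled$ratio
  expect_equal(melting_temperature(scaled)$mT, fit$mT, tolerance = 1e-12)

  # monotone ramp: no transition captured
  ramp <- assay_table(data.frame(series = "s1", temp = 20:95,
                                 ratio = 0.8 + 0.001 * (20:95)), "melt_curve")
  expect_true(melting_temperature(ramp)$no_transition)

  # 1% noise: recovered mT scatters by well under half a degree
  mts <- vapply(1:50, function(s) {
    melting_temperature(sim_melt_curve(
      study$mT, noise = noise_spec(sd = 0.0025, seed = s, replicates = 2)))$mT
  }, numeric(1))
  expect_lt(stats::sd(mts), 0.5)
  expect_equal(mean(mts), study$mT, tolerance = 0.5 / study$mT)
})

test_that("Gaussian profile fits report the FWHM of the fitted curve", {
  expect_equal(omega_to_fwhm(1), sqrt(2 * log(2)), tolerance = 1e-12)
  expect_equal(omega_to_fwhm(1), 1.17741, tolerance = 1e-5)

  prof <- sim_gaussian_profile(study$fwhm, area = 1e4, offset = 10)
  fit <- fit_profile_fwhm(prof)
  expect_true(fit$converged)
  expect_equal(fit$fwhm, study$fwhm, tolerance = 1e-4)
  expect_equal(fit$fwhm, fit$omega * sqrt(2 * log(2)), tolerance = 1e-12)

  # the fitted curve's half-maximum crossings are exactly one FWHM apart
  peak <- gaussian_profile(fit$xc, fit$y0, fit$a, fit$xc, fit$omega)
  half <- fit$y0 + (peak - fit$y0) / 2
  lo <- stats::uniroot(function(x) gaussian_profile(x, fit$y0, fit$a, fit$xc,
                                                    fit$omega) - half,
                       c(fit$xc - 3 * fit$fwhm, fit$xc), tol = 1e-12)$root
  hi <- stats::uniroot(function(x) gaussian_profile(x, fit$y0, fit$a, fit$xc,
                                                    fit$omega) - half,
                       c(fit$xc, fit$xc + 3 * fit$fwhm), tol = 1e-12)$root
  expect_equal(hi - lo, fit$fwhm, tolerance = 1e-8)

  # adding a constant offset leaves the width untouched (absorbed by y0)
  shifted <- prof
  shifted$intensity <- shifted$intensity + 250
  fit2 <- fit_profile_fwhm(shifted)
  expect_equal(fit2$fwhm, fit$fwhm, tolerance = 1e-6)
  expect_equal(fit2$y0, fit$y0 + 250, tolerance = 1e-4)

  # per-filament summary over several noisy profiles
  tab <- sim_gaussian_profile(study$fwhm, area = 1e4, offset = 10,
                              noise = noise_spec(
                                sd = 0.05 * gauss_peak_height(study$fwhm, 1e4),
                                seed = 2, replicates = 16))
  s <- profile_fwhm_summary(tab)
  expect_equal(s$n, 16L)
  expect_equal(s$fwhm_mean, study$fwhm, tolerance = 0.05)
})
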