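test_that("the second-order FP model satisfies its structural invariants", {
  set.seed(101)
  for (i in 1:25) {
    a0 <- 10^stats::runif(1, -10, -7)
    b0 <- 10^stats::runif(1, -10, -7)
    if (abs(a0 - b0) < 1e-5 * a0) b0 <- b0 * 1.1
    k <- 10^stats::runif(1, 3, 6)
    ff <- stats::runif(1, 20, 80)
    fb <- ff + stats::runif(1, 50, 300)
    t <- c(0, 10^seq(0, 8, length.out = 40))
    fp <- fp_second_order(t, k, ff, fb, a0, b0)
    expect_equal(fp[1], ff, tolerance = 1e-14)       # FP(0) = FP_free
    expect_true(all(diff(fp) >= -1e-9 * (fb - ff)))  # monotone toward bound
    # implied product concentration never exceeds the limiting reagent
    frac <- (fp - fb) / (ff - fb)                    # remaining A / A0
    product <- a0 * (1 - frac)
    expect_true(all(product <= min(a0, b0) * (1 + 1e-9)))
  }
})

test_that("fit_second_order recovers parameters from noiseless data", {
  tc <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0)
  fit <- fit_second_order(tc)
  expect_true(fit$converged)
  expect_equal(fit$k_app, 1e5, tolerance = 1e-6)
  expect_equal(fit$fp_free, 50, tolerance = 1e-4)
  expect_equal(fit$fp_bound, 250, tolerance = 1e-4)

  # with an applied (and recorded) dead time the fit still recovers k_app
  tcd <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0,
                                 dead_time = 30)
  fitd <- fit_second_order(tcd)
  expect_equal(fitd$k_app, 1e5, tolerance = 1e-6)
  # ignoring a real dead time biases the rate
  fit0 <- fit_second_order(tcd, dead_time = 0)
  expect_gt(abs(fit0$k_app - 1e5) / 1e5, abs(fitd$k_app - 1e5) / 1e5)

  expect_error(fit_second_order(time_course(1:4, 1:4, 1e-9, 2e-9)), "5")
})

test_that("fit_second_order keeps median k_app error under 5% at 2% noise", {
  errs <- vapply(1:50, function(s) {
    tc <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0,
                                  noise = noise_spec(sd = study$fp_sd_2pct,
                                                     seed = s, replicates = 2))
    abs(fit_second_order(tc)$k_app - 1e5) / 1e5
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("choose_model selects linear only for non-plateauing reactions", {
  # fast reaction: ~99% completion by the end of the window
  fast <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0)
  ffit <- fit_second_order(fast)
  expect_identical(choose_model(fast, ffit), "second_order")

  # truncated slow reaction: a few percent completion
  slow <- sim_labeling_timecourse(1e2, 50, 250, study$a0, study$b0,
                                  times = seq(0, 3600, 60))
  sfit <- fit_second_order(slow)
  expect_identical(choose_model(slow, sfit), "linear")
  expect_identical(fit_kinetics(slow)$model, "linear")

  # completion exactly at the threshold is (inclusively) second_order,
  # just above it selects linear
  span <- ffit$fp_bound - ffit$fp_free
  pred_end <- fp_second_order(max(fast$t) + ffit$dead_time, ffit$k_app,
                              ffit$fp_free, ffit$fp_bound, fast$a0, fast$b0)
  completion <- (pred_end - ffit$fp_free) / span
  expect_identical(choose_model(fast, ffit, threshold = completion),
                   "second_order")
  expect_identical(choose_model(fast, ffit,
                                threshold = completion * (1 + 1e-9)),
                   "linear")

  # a constant trace carries no rate information
  flat <- time_course(seq(0, 600, 60), rep(50, 11), study$a0, study$b0)
  expect_lt(abs(fit_kinetics(flat)$slope0), 1e-8)
})

test_that("initial_slope matches the analytic derivative and scales with b0", {
  tc <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0)
  fit <- fit_second_order(tc)
  s <- initial_slope(fit, tc)
  # central finite difference of the model near t = 0
  h <- 1e-6
  fd <- (fp_second_order(h, fit$k_app, fit$fp_free, fit$fp_bound,
                         study$a0, study$b0) -
           fp_second_order(0, fit$k_app, fit$fp_free, fit$fp_bound,
                           study$a0, study$b0)) / h
  expect_equal(s, fd, tolerance = 1e-6)

  # slope is linear in b0 and vanishes with the rate
  tc2 <- sim_labeling_timecourse(1e5, 50, 250, study$a0, 2 * study$b0)
  fit2 <- fit_second_order(tc2)
  expect_equal(initial_slope(fit2, tc2) / s, 2, tolerance = 1e-3)
  fit0 <- fit
  fit0$k_app <- 0
  expect_equal(initial_slope(fit0, tc), 0)
})

test_that("fit_background recovers the pseudo-first-order half-time", {
  t <- seq(0, 40000, 400)
  y <- 30 + (200 - 30) * (1 - exp(-1e-4 * t))
  fit <- fit_background(time_course(t, y, 12.5e-6, 50e-9))
  expect_true(fit$converged)
  expect_equal(fit$t_half, log(2) / 1e-4, tolerance = 1e-4)
  expect_equal(fit$t_half * fit$k_obs, log(2), tolerance = 1e-12)

  # effectively unreactive protein: half-time unbounded, flagged
  y2 <- 30 + 1e-4 * (1 - exp(-1e-9 * t))
  fit2 <- fit_background(time_course(t, y2 + 0, 12.5e-6, 50e-9))
  expect_true(fit2$unbounded)
})
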