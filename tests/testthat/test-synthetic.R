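test_that("labeling time-course generator obeys the analytic limits", {
  # no reaction: constant at fp_free
  tc0 <- sim_labeling_timecourse(0, 50, 250, study$a0, study$b0,
                                 times = seq(0, 1000, 100))
  expect_equal(tc0$fp, rep(50, length(tc0$t)))

  # t = 0 starts at fp_free; with protein in excess the signal ends at fp_bound
  tc <- sim_labeling_timecourse(1e5, 50, 250, study$a0, study$b0,
                                times = c(0, 10^(1:9)))
  expect_equal(tc$fp[1], 50)
  expect_equal(tc$fp[length(tc$fp)], 250, tolerance = 1e-9)

  # the a0 = b0 case equals the numeric limit of the general form
  t <- seq(0, 1e5, length.out = 50)
  lim <- fp_second_order(t, 1e5, 50, 250, 1e-9, 1e-9)
  up <- fp_second_order(t, 1e5, 50, 250, 1e-9, 1e-9 * (1 + 2e-6))
  dn <- fp_second_order(t, 1e5, 50, 250, 1e-9, 1e-9 * (1 - 2e-6))
  expect_equal(up, lim, tolerance = 1e-6)
  expect_equal(dn, lim, tolerance = 1e-6)
})

test_that("EC50 dataset generator uses the stated dilution design and is pure", {
  tab <- sim_ec50_dataset(study$ec50_delta3, study$k_max, 50, 250)
  concs <- sort(unique(tab$conc), decreasing = TRUE)
  expect_length(concs, 11L)
  expect_equal(concs[1], 1000e-9)
  expect_equal(concs[11], 1000e-9 / 2^10)  # 0.977 nM
  expect_equal(concs[-11] / concs[-1], rep(2, 10))

  # at c = EC50 the generated rate is k_max / 2 exactly
  expect_equal(ec50_hyperbolic(study$ec50_delta3, study$ec50_delta3,
                               top = study$k_max),
               study$k_max / 2)

  # determinism: same seed, bit-identical output
  a <- sim_ec50_dataset(10e-9, 1e5, 50, 250,
                        noise = noise_spec(sd = 4, seed = 42, replicates = 2))
  b <- sim_ec50_dataset(10e-9, 1e5, 50, 250,
                        noise = noise_spec(sd = 4, seed = 42, replicates = 2))
  expect_identical(a$fp, b$fp)
  c <- sim_ec50_dataset(10e-9, 1e5, 50, 250,
                        noise = noise_spec(sd = 4, seed = 43, replicates = 2))
  expect_false(identical(a$fp, c$fp))
})

test_that("saturation generator matches an independently coded isotherm", {
  cs <- c(0.3, 2, 6.5, 40, 900) * 1e-9
  tab <- sim_saturation_binding(6.5e-9, top = 300, bottom = 60, concs = cs,
                                noise = noise_spec(replicates = 1))
  # independent implementation of one-site specific binding
  ref <- vapply(cs, function(c) 60 + (300 - 60) / (1 + 6.5e-9 / c), numeric(1))
  got <- tab$fp[match(cs, tab$conc)]
  expect_equal(sort(got), sort(ref), tolerance = 1e-12)

  # midpoint and saturation limits
  expect_equal(tab$fp[tab$conc == 6.5e-9], (300 + 60) / 2)
  big <- sim_saturation_binding(6.5e-9, 300, 60, concs = c(1, 1e-3, 1e-6),
                                noise = noise_spec(replicates = 1))
  expect_equal(max(big$fp), 300, tolerance = 1e-3)
})

test_that("BLI generator agrees with an ODE integration of the 1:1 model", {
  skip_if_not_installed("deSolve")
  kon <- 5e4; koff <- 2e-4; rmax <- 1.2; conc <- 100e-9
  tab <- sim_bli_sensorgrams(kon, koff, rmax, concs = c(conc, 50e-9, 25e-9),
                             t_baseline = 10, t_assoc = 200, t_dissoc = 200,
                             hz = 1)
  tr <- tab[tab$series == "conc01", ]
  # dR/dt = kon c (rmax - R) - koff R with c = conc during association
  # (t in [10, 210]) and c = 0 during dissociation
  rhs <- function(t, y, p) {
    list(p$kon * p$c * (p$rmax - y) - p$koff * y)
  }
  ta <- tr$time[tr$phase == "association"]
  td <- tr$time[tr$phase == "dissociation"]
  o1 <- deSolve::ode(y = c(R = 0), times = c(ta, 210), func = rhs,
                     parms = list(kon = kon, koff = koff, rmax = rmax,
                                  c = conc),
                     rtol = 1e-10, atol = 1e-12)
  o2 <- deSolve::ode(y = c(R = unname(o1[nrow(o1), "R"])), times = td,
                     func = rhs,
                     parms = list(kon = kon, koff = koff, rmax = rmax, c = 0),
                     rtol = 1e-10, atol = 1e-12)
  got <- tr$response[tr$phase != "baseline"]
  ref <- c(unname(o1[seq_along(ta), "R"]), unname(o2[, "R"]))
  expect_equal(got, ref, tolerance = 1e-6)

  # degenerate designs
  z <- sim_bli_sensorgrams(kon, koff, rmax, concs = c(0, 50e-9, 25e-9),
                           t_baseline = 10, t_assoc = 50, t_dissoc = 50, hz = 1)
  expect_true(all(z$response[z$series == "conc01"] == 0))
  nf <- sim_bli_sensorgrams(kon, 0, rmax, concs = c(100e-9, 50e-9, 25e-9),
                            t_baseline = 10, t_assoc = 50, t_dissoc = 50, hz = 1)
  dis <- nf$response[nf$series == "conc01" & nf$phase == "dissociation"]
  expect_equal(diff(range(dis)), 0)
})

test_that("Gaussian profile generator has the right peak, width and area", {
  tab <- sim_gaussian_profile(84, area = 1e4, offset = 10, pixel_nm = 2,
                              window_nm = 6 * 84)
  expect_equal(tab$position[which.max(tab$intensity)], 0)

  # half-maximum crossings are one FWHM apart, to one pixel
  half <- 10 + (max(tab$intensity) - 10) / 2
  left <- tab$position <= 0
  lo <- stats::approx(tab$intensity[left], tab$position[left], half)$y
  hi <- stats::approx(tab$intensity[!left], tab$position[!left], half)$y
  expect_equal(hi - lo, 84, tolerance = 2 / 84)

  # the area parameter is recovered by quadrature within 1%
  area <- pracma::trapz(tab$position, tab$intensity - 10)
  expect_equal(area, 1e4, tolerance = 0.01)

  expect_error(sim_gaussian_profile(84, window_nm = 100), "window")
  expect_error(sim_gaussian_profile(84, pixel_nm = 0), "pixel_nm")
})

test_that("melt-curve generator is a symmetric sigmoid on the stated grid", {
  tab <- sim_melt_curve(46.3, noise = noise_spec(replicates = 1))
  expect_equal(range(tab$temp), c(20, 95))
  expect_equal(unique(diff(tab$temp)), 1)

  # symmetry about the inflection (flat baseline)
  r <- function(T) {
    sim_melt_curve(50, temps = c(20, T, 95),
                   noise = noise_spec(replicates = 1))$ratio[2]
  }
  for (d in c(1, 3.5, 7)) {
    expect_equal(r(50 + d) + r(50 - d), 2 * r(50), tolerance = 1e-12)
  }

  # analytic first derivative is maximal at mT
  tt <- seq(20, 95, 0.01)
  mu <- sim_melt_curve(46.3, temps = tt, noise = noise_spec(replicates = 1))$ratio
  expect_equal(tt[which.max(diff(mu))], 46.3, tolerance = 0.02)

  expect_error(sim_melt_curve(10), "mT")
  expect_error(sim_melt_curve(50, slope = -1), "slope")
})

test_that("NNK read generator respects the codon alphabet and the profile", {
  tpl <- strrep("GATGCT", 4)  # 8 codons
  reads <- sim_nnk_reads(tpl, c(3, 6), c(A = 0.25, G = 0.25, W = 0.5),
                         n = 400, seed = 5)
  expect_equal(nrow(reads), 400L)
  third_base <- substr(reads$seq, 9, 9)  # codon 3 occupies bases 7-9
  expect_true(all(third_base %in% c("G", "T")))
  third_base6 <- substr(reads$seq, 18, 18)
  expect_true(all(third_base6 %in% c("G", "T")))

  # degenerate profile: every read carries the single residue
  only_w <- sim_nnk_reads(tpl, 3, c(W = 1), n = 50, seed = 6)
  expect_true(all(substr(only_w$seq, 7, 9) == "TGG"))

  # empirical frequencies match the profile within 3 binomial SE at n = 50000
  n <- 50000
  prof <- c(A = 0.2, L = 0.35, S = 0.35, `*` = 0.1)
  big <- sim_nnk_reads(tpl, 4, prof, n = n, seed = 7)
  des <- library_design(tpl, 4)
  freq <- aa_frequencies(big, des)$freq[1, names(prof)]
  se <- sqrt(prof * (1 - prof) / n)
  expect_true(all(abs(freq - prof) <= 3 * se))

  expect_error(sim_nnk_reads(tpl, 9, c(W = 1), 10), "range")
})
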