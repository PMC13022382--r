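# Synthetic-data generators.
#
# Every input the pipeline consumes can be generated with the assay designs
# used in the characterization experiments (twofold 1000-0.98 nM peptide
# dilution series with two technical replicates, fivefold saturation
# titrations in triplicate, 300-2 nM BLI concentration series, 20-95 degC
# nanoDSF ramps at 1 degC steps, NNK-codon libraries), so every fitting stage
# is testable by parameter recovery without any instrument data. All
# generators are pure functions of (parameters, seed): the root seed of the
# noise specification fans out to per-series child seeds via [child_seed].
# Noise is additive i.i.d. Gaussian on the observable — the standard
# plate-reader assumption; replicate counts are part of the design.

#' Noise specification for synthetic data
#'
#' @param sd standard deviation of the additive Gaussian noise, in the units
#'   of the observable (mP, response nm, intensity...).
#' @param seed integer root seed.
#' @param replicates number of technical replicates (>= 1).
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sd = 0, seed = 1, replicates = 1) {
  check_scalar(sd, "sd", nonneg = TRUE)
  check_scalar(replicates, "replicates")
  if (replicates < 1) stop_badarg("`replicates` must be >= 1")
  structure(list(sd = sd, seed = as.integer(seed),
                 replicates = as.integer(replicates)),
            class = "noise_spec")
}

#' Simulate a single labeling time course
#'
#' The noiseless signal follows the second-order FP model exactly (evaluated
#' at `times + dead_time`, emulating the delay between substrate addition and
#' the first recorded point); Gaussian noise of `noise$sd` is added per point
#' and replicate, and replicates are averaged into the returned
#' [time_course] (with per-time SD retained).
#'
#' @param k_app apparent second-order rate constant, 1/M/s (>= 0).
#' @param fp_free,fp_bound FP endpoints, mP.
#' @param a0,b0 substrate and protein concentrations, M.
#' @param times observation time grid, s (>= 0).
#' @param noise a [noise_spec].
#' @param conc condition (peptide) concentration recorded on the trace, M.
#' @param dead_time dead time in seconds the generator applies (default 0).
#' @param stream child-seed stream index (used by dataset-level generators).
#' @return a [time_course].
#' @export
sim_labeling_timecourse <- function(k_app, fp_free, fp_bound, a0, b0,
                                    times = seq(0, 36000, by = 300),
                                    noise = noise_spec(), conc = NA_real_,
                                    dead_time = 0, stream = 0) {
  if (any(times < 0)) stop_badarg("times must be >= 0")
  mu <- fp_second_order(times + dead_time, k_app, fp_free, fp_bound, a0, b0)
  reps <- with_seed(child_seed(noise$seed, stream), {
    vapply(seq_len(noise$replicates),
           function(r) mu + stats::rnorm(length(mu), 0, noise$sd),
           numeric(length(mu)))
  })
  reps <- matrix(reps, nrow = length(mu))
  time_course(times, rowMeans(reps), a0 = a0, b0 = b0, conc = conc,
              dead_time = dead_time,
              fp_sd = if (noise$replicates > 1) apply(reps, 1, stats::sd) else NULL)
}

#' Simulate a full EC50 labeling-kinetics dataset
#'
#' For each peptide concentration `c` of the dilution series, the
#' concentration-dependent rate `k_app(c) = k_max c / (EC50 + c)` is computed
#' and a second-order FP time course is generated from it; replicates carry
#' independent noise. The default dilution series is the twofold series from
#' 1000 nM to 0.98 nM (11 concentrations); the default grid records 10 h at
#' 5 min intervals.
#'
#' @param ec50 half-maximal complementing concentration, M.
#' @param k_max rate at saturating peptide, 1/M/s.
#' @param fp_free,fp_bound FP endpoints, mP.
#' @param a0,b0 substrate and protein concentrations, M.
#' @param concs strictly decreasing dilution series, M (>= 6 values).
#' @param times observation grid, s.
#' @param noise a [noise_spec].
#' @param dead_time dead time applied by the generator, s.
#' @return an [assay_table] of kind `fp_timecourse` with a `replicate`
#'   column; `meta` records `a0`, `b0`, `dead_time` and the ground truth.
#' @export
sim_ec50_dataset <- function(ec50, k_max, fp_free, fp_bound,
                             a0 = 0.5e-9, b0 = 2.5e-9,
                             concs = 1000e-9 * 2^-(0:10),
                             times = seq(0, 36000, by = 300),
                             noise = noise_spec(), dead_time = 0) {
  if (length(concs) < 6 || any(diff(concs) >= 0)) {
    stop_badarg("`concs` must be a strictly decreasing series of >= 6 values")
  }
  rows <- list()
  for (i in seq_along(concs)) {
    cc <- concs[i]
    k <- ec50_hyperbolic(cc, ec50, top = k_max)
    mu <- fp_second_order(times + dead_time, k, fp_free, fp_bound, a0, b0)
    for (r in seq_len(noise$replicates)) {
      eps <- with_seed(child_seed(noise$seed, (i - 1) * noise$replicates + r),
                       stats::rnorm(length(mu), 0, noise$sd))
      rows[[length(rows) + 1L]] <- data.frame(
        series = sprintf("c%02d_r%d", i, r), conc = cc, time = times,
        fp = mu + eps, replicate = r)
    }
  }
  assay_table(do.call(rbind, rows), "fp_timecourse",
              meta = list(a0 = a0, b0 = b0, dead_time = dead_time,
                          truth = list(ec50 = ec50, k_max = k_max,
                                       fp_free = fp_free, fp_bound = fp_bound)))
}

#' Simulate an FP saturation-binding titration
#'
#' Noiseless signal `FP(c) = bottom + (top - bottom) c / (kd + c)`; the
#' default titration is a fivefold dilution series from 10 uM (10 points),
#' measured in triplicate.
#'
#' @param kd dissociation constant, M (> 0).
#' @param top,bottom FP at saturation and at zero protein, mP.
#' @param concs titrated protein concentrations, M (> 0).
#' @param noise a [noise_spec].
#' @return an [assay_table] of kind `saturation` with a `replicate` column.
#' @export
sim_saturation_binding <- function(kd, top, bottom,
                                   concs = 1e-5 * 5^-(0:9),
                                   noise = noise_spec(replicates = 3)) {
  check_scalar(kd, "kd", positive = TRUE)
  if (any(concs <= 0)) stop_badarg("concentrations must be > 0")
  concs <- sort(concs, decreasing = TRUE)
  mu <- ec50_hyperbolic(concs, kd, top = top, bottom = bottom)
  rows <- lapply(seq_len(noise$replicates), function(r) {
    eps <- with_seed(child_seed(noise$seed, r),
                     stats::rnorm(length(mu), 0, noise$sd))
    data.frame(series = sprintf("rep%d", r),
               conc = rev(concs), fp = rev(mu + eps), replicate = r)
  })
  assay_table(do.call(rbind, rows), "saturation",
              meta = list(truth = list(kd = kd, top = top, bottom = bottom)))
}

#' Simulate multi-concentration BLI sensorgrams (1:1 model)
#'
#' Each trace records a baseline phase (response 0), an association phase
#' `R(t) = R_eq (1 - e^{-(kon c + koff) t})` with
#' `R_eq = rmax c / (K_d + c)`, and a dissociation phase decaying
#' mono-exponentially with `koff` from the association end point. Optional
#' per-trace linear drift and Gaussian noise are added. The default design is
#' the twofold 300-2.3 nM analyte series with 60 s baseline, 300 s
#' association and 300 s dissociation at 5 Hz.
#'
#' @param kon association rate constant, 1/M/s (> 0).
#' @param koff dissociation rate constant, 1/s (> 0).
#' @param rmax maximal surface response, nm.
#' @param concs analyte concentrations, M.
#' @param t_baseline,t_assoc,t_dissoc phase durations, s (`t_assoc` > 0).
#' @param hz acquisition rate, points per second.
#' @param noise a [noise_spec].
#' @param drift linear drift, response units per second (default 0).
#' @return an [assay_table] of kind `sensorgram`.
#' @export
sim_bli_sensorgrams <- function(kon, koff, rmax,
                                concs = 300e-9 * 2^-(0:7),
                                t_baseline = 60, t_assoc = 300,
                                t_dissoc = 300, hz = 5,
                                noise = noise_spec(), drift = 0) {
  check_scalar(kon, "kon", positive = TRUE)
  check_scalar(koff, "koff", positive = FALSE, nonneg = TRUE)
  if (t_assoc <= 0) stop_badarg("`t_assoc` must be > 0")
  kd <- koff / kon
  dt <- 1 / hz
  tb <- seq(0, t_baseline - dt, by = dt)
  ta <- seq(t_baseline, t_baseline + t_assoc - dt, by = dt)
  td <- seq(t_baseline + t_assoc, t_baseline + t_assoc + t_dissoc, by = dt)
  rows <- lapply(seq_along(concs), function(i) {
    cc <- concs[i]
    req <- if (cc > 0) rmax * cc / (kd + cc) else 0
    kobs <- kon * cc + koff
    r_assoc <- req * (1 - exp(-kobs * (ta - t_baseline)))
    r_end <- req * (1 - exp(-kobs * t_assoc))
    r_dis <- r_end * exp(-koff * (td - (t_baseline + t_assoc)))
    tt <- c(tb, ta, td)
    rr <- c(rep(0, length(tb)), r_assoc, r_dis) + drift * tt
    eps <- with_seed(child_seed(noise$seed, i),
                     stats::rnorm(length(tt), 0, noise$sd))
    data.frame(series = sprintf("conc%02d", i), conc = cc, time = tt,
               response = rr + eps,
               phase = rep(c("baseline", "association", "dissociation"),
                           c(length(tb), length(ta), length(td))))
  })
  assay_table(do.call(rbind, rows), "sensorgram",
              meta = list(truth = list(kon = kon, koff = koff, kd = kd,
                                       rmax = rmax),
                          t_assoc = t_assoc))
}

#' Simulate a Gaussian intensity line profile
#'
#' Samples the area-parameterized Gaussian
#' `y = y0 + A/(omega sqrt(pi/2)) exp(-2 (x - xc)^2 / omega^2)` with
#' `omega = fwhm / sqrt(2 ln 2)` on a uniform pixel grid centred on the peak.
#'
#' @param fwhm full width at half maximum, nm (> 0).
#' @param area area parameter A (intensity x nm).
#' @param offset baseline intensity y0.
#' @param center peak center, nm.
#' @param pixel_nm pixel size, nm (> 0).
#' @param window_nm profile length, nm (must be >= 3 x fwhm).
#' @param noise a [noise_spec].
#' @return an [assay_table] of kind `line_profile`, one series per replicate.
#' @export
sim_gaussian_profile <- function(fwhm, area = 1e4, offset = 10, center = 0,
                                 pixel_nm = 20, window_nm = 600,
                                 noise = noise_spec()) {
  check_scalar(fwhm, "fwhm", positive = TRUE)
  check_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  if (window_nm < 3 * fwhm) stop_badarg("`window_nm` must be >= 3 x fwhm")
  omega <- fwhm / sqrt(2 * log(2))
  x <- seq(-window_nm / 2, window_nm / 2, by = pixel_nm) + center
  mu <- gaussian_profile(x, offset, area, center, omega)
  rows <- lapply(seq_len(noise$replicates), function(r) {
    eps <- with_seed(child_seed(noise$seed, r),
                     stats::rnorm(length(mu), 0, noise$sd))
    data.frame(series = sprintf("profile%d", r), position = x,
               intensity = mu + eps)
  })
  assay_table(do.call(rbind, rows), "line_profile",
              meta = list(truth = list(fwhm = fwhm, omega = omega,
                                       area = area, offset = offset,
                                       center = center)))
}

#' Simulate a nanoDSF 350/330 ratio melt curve
#'
#' Sigmoidal unfolding transition with inflection at the melting temperature:
#' `ratio(T) = (b0 + b1 T) + amplitude / (1 + exp(-slope (T - mT)))`. The
#' default grid is 1 degC steps from 20 to 95 degC.
#'
#' @param mT melting temperature, degC (must lie in the scanned range
#'   20-95 degC).
#' @param slope sigmoid steepness, 1/degC (> 0).
#' @param amplitude transition amplitude of the 350/330 ratio.
#' @param baseline,baseline_slope pre-transition baseline intercept and slope
#'   (per degC).
#' @param temps temperature grid, degC.
#' @param noise a [noise_spec].
#' @return an [assay_table] of kind `melt_curve`, one series per replicate.
#' @export
sim_melt_curve <- function(mT, slope = 0.7, amplitude = 0.25,
                           baseline = 0.85, baseline_slope = 0,
                           temps = seq(20, 95, by = 1),
                           noise = noise_spec(replicates = 2)) {
  if (mT < 20 || mT > 95) stop_badarg("`mT` must lie within 20-95 degC")
  check_scalar(slope, "slope", positive = TRUE)
  mu <- baseline + baseline_slope * temps +
    amplitude / (1 + exp(-slope * (temps - mT)))
  rows <- lapply(seq_len(noise$replicates), function(r) {
    eps <- with_seed(child_seed(noise$seed, r),
                     stats::rnorm(length(mu), 0, noise$sd))
    data.frame(series = sprintf("scan%d", r), temp = temps, ratio = mu + eps)
  })
  assay_table(do.call(rbind, rows), "melt_curve",
              meta = list(truth = list(mT = mT, slope = slope,
                                       amplitude = amplitude)))
}

# All 32 NNK codons (N = A/C/G/T at positions 1-2, K = G/T at position 3) and
# the amino acid (or *) each encodes under the standard genetic code.
nnk_codon_table <- function() {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), c("G", "T"), paste0))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  data.frame(codon = codons, aa = aas, stringsAsFactors = FALSE)
}

#' Simulate reads from an NNK saturation-mutagenesis library
#'
#' Reads equal the template except at the randomized codons, which are drawn
#' as NNK codons (third base G or T) realizing amino acids according to the
#' per-position profile; for a drawn amino acid, the synonymous NNK codons
#' are used uniformly. Optional uniform substitution errors emulate
#' sequencing noise. Deterministic under `seed`.
#'
#' @param template DNA template (A/C/G/T string), length divisible by 3 over
#'   the analyzed window.
#' @param positions 1-based codon indices of the randomized positions.
#' @param profile per-position amino-acid weights: a named numeric vector
#'   (recycled across positions) or a list of one named vector per position.
#'   Names are one-letter codes (`*` allowed); weights are normalized per
#'   position. Every named residue must be NNK-encodable (all 20 amino acids
#'   and `*` are).
#' @param n number of reads.
#' @param seed integer seed.
#' @param error_rate per-base substitution error probability (default 0).
#' @return data frame with columns `id`, `seq`.
#' @export
sim_nnk_reads <- function(template, positions, profile, n, seed = 1,
                          error_rate = 0) {
  template <- toupper(template)
  n_codons <- nchar(template) %/% 3
  if (any(positions < 1 | positions > n_codons)) {
    stop_badarg("randomized codon position out of range")
  }
  if (anyDuplicated(positions)) stop_badarg("duplicated randomized positions")
  if (error_rate < 0 || error_rate >= 1) stop_badarg("invalid error_rate")
  if (!is.list(profile)) profile <- rep(list(profile), length(positions))
  stopifnot(length(profile) == length(positions))
  tab <- nnk_codon_table()
  codons_for <- split(tab$codon, tab$aa)

  tpl <- strsplit(template, "")[[1]]
  with_seed(seed, {
    mat <- matrix(rep(tpl, n), nrow = n, byrow = TRUE)
    for (j in seq_along(positions)) {
      w <- profile[[j]]
      bad <- setdiff(names(w), names(codons_for))
      if (length(bad) > 0) {
        stop_badarg("profile residue(s) not NNK-encodable: ",
                    paste(bad, collapse = ", "))
      }
      aa_draw <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
      codon_draw <- vapply(aa_draw, function(a) {
        cs <- codons_for[[a]]
        cs[sample.int(length(cs), 1)]
      }, character(1))
      cstart <- (positions[j] - 1) * 3 + 1
      cm <- do.call(rbind, strsplit(codon_draw, ""))
      mat[, cstart:(cstart + 2)] <- cm
    }
    if (error_rate > 0) {
      hit <- which(matrix(stats::runif(length(mat)) < error_rate,
                          nrow = nrow(mat)))
      if (length(hit) > 0) {
        b <- c("A", "C", "G", "T")
        mat[hit] <- vapply(mat[hit],
                           function(x) sample(setdiff(b, x), 1), character(1))
      }
    }
    data.frame(id = sprintf("read%06d", seq_len(n)),
               seq = apply(mat, 1, paste0, collapse = ""),
               stringsAsFactors = FALSE)
  })
}
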