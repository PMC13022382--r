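# Binding affinity: equilibrium K_d from FP saturation titrations, and kinetic
# k_on/k_off/K_d from bio-layer interferometry sensorgrams with a global 1:1
# Langmuir model.

#' Fit a saturation binding isotherm (K_d from an FP titration)
#'
#' A fixed tracer (fluorophore-peptide conjugate, ~1 nM) is titrated with the
#' binding protein in large excess, so free protein ~ total protein and
#' `FP(c) = bottom + (top - bottom) c / (K_d + c)` (three parameters, Hill
#' slope 1). This is the same hyperbola as the dose-response model, so K_d is
#' fitted by the same profiled least squares, and the Monte Carlo CI machinery
#' is reused when `n_mc > 0`.
#'
#' @param table an [assay_table] of kind `saturation` (replicates averaged per
#'   concentration first), or a data frame with `conc` (M) and `fp` columns.
#' @param n_mc if positive, attach a Monte Carlo percentile CI with this many
#'   replicates (5% worst refits discarded).
#' @param seed seed for the Monte Carlo draw.
#' @return a `saturation_fit` with `kd` (M), `top`, `bottom`, `sse`,
#'   `inverted` (TRUE when the fitted response decreases with concentration),
#'   `range_warning` (K_d more than 10x outside the titrated range), and `ci`.
#' @export
fit_saturation_kd <- function(table, n_mc = 0, seed = 1) {
  if (inherits(table, "assay_table")) {
    stopifnot(assay_kind(table) == "saturation")
  }
  conc <- tapply(table$fp, table$conc, mean)
  x <- as.numeric(names(conc))
  y <- as.numeric(conc)
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (length(x) < 4) stop_badarg("need at least 4 distinct concentrations")
  pf <- .profile_dr_fit(x, y, "hyperbolic")
  range_warning <- pf$ec50 > 10 * max(x) || pf$ec50 < min(x) / 10
  if (range_warning) {
    warning("fitted K_d (", signif(pf$ec50, 4),
            " M) lies > 10x outside the titrated range", call. = FALSE)
  }
  fit <- structure(list(kd = pf$ec50, top = pf$top, bottom = pf$bottom,
                        sse = pf$sse,
                        residual_sd = sqrt(pf$sse / max(length(y) - 3, 1)),
                        fitted = pf$fitted, conc = x, fp = y,
                        inverted = pf$top < pf$bottom,
                        range_warning = range_warning,
                        converged = !pf$at_boundary,
                        ci = c(NA_real_, NA_real_)),
                   class = "saturation_fit")
  if (n_mc > 0) {
    dr <- structure(list(ec50 = fit$kd, k_max = fit$top, bottom = fit$bottom,
                         sse = fit$sse, residual_sd = fit$residual_sd,
                         fitted = fit$fitted, form = "hyperbolic",
                         n = length(y), conc = x, rate = y,
                         rate_sd = rep(NA_real_, length(y)),
                         converged = fit$converged),
                    class = "dose_response_fit")
    dr <- monte_carlo_ci(dr, n = n_mc, seed = seed)
    fit$ci <- dr$ci
  }
  fit
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit: K_d=%.4g nM, bottom=%.4g, top=%.4g mP%s>\n",
              x$kd / 1e-9, x$bottom, x$top,
              if (x$inverted) " (inverted)" else ""))
  if (all(is.finite(x$ci))) {
    cat(sprintf("  95%% CI: (%.4g - %.4g) nM\n", x$ci[1] / 1e-9, x$ci[2] / 1e-9))
  }
  invisible(x)
}

#' @export
as_report.saturation_fit <- function(fit) {
  list(model = "saturation_1site", kd = fit$kd, kd_ci_low = fit$ci[1],
       kd_ci_high = fit$ci[2], top = fit$top, bottom = fit$bottom,
       sse = fit$sse, inverted = fit$inverted,
       range_warning = fit$range_warning, converged = fit$converged)
}

# --- BLI ---------------------------------------------------------------------

split_sensorgrams <- function(table) {
  stopifnot(inherits(table, "assay_table"), assay_kind(table) == "sensorgram")
  lapply(split(as.data.frame(table), table$series), function(d) {
    d[order(d$time), , drop = FALSE]
  })
}

#' Preprocess BLI sensorgrams: baseline alignment and smoothing
#'
#' Each trace is baseline-aligned by subtracting the mean response of its
#' baseline phase (idempotent: aligning twice equals aligning once), then
#' smoothed with a Savitzky-Golay filter to remove high-frequency noise.
#' Phase labels are preserved. Window 11 points / order 2 are conventional
#' defaults for 5 Hz sensorgrams.
#'
#' @param table an [assay_table] of kind `sensorgram`.
#' @param sg_window odd filter window length in points (`> sg_order`); set to
#'   0 to skip smoothing.
#' @param sg_order polynomial order of the filter.
#' @return the preprocessed [assay_table].
#' @export
bli_preprocess <- function(table, sg_window = 11, sg_order = 2) {
  sgs <- split_sensorgrams(table)
  if (sg_window > 0) {
    if (sg_window %% 2 == 0 || sg_window <= sg_order) {
      stop_badarg("sg_window must be odd and greater than sg_order")
    }
  }
  out <- lapply(sgs, function(d) {
    base <- d$response[d$phase == "baseline"]
    if (length(base) < 5) {
      stop_badarg("baseline phase needs at least 5 points (series ",
                  d$series[1], ")")
    }
    d$response <- d$response - mean(base)
    if (sg_window > 0) {
      if (sg_window >= nrow(d)) {
        stop_badarg("sg_window must be shorter than the trace")
      }
      d$response <- as.numeric(
        signal::sgolayfilt(d$response, p = sg_order, n = sg_window))
    }
    d
  })
  assay_table(do.call(rbind, out), "sensorgram", meta = assay_meta(table))
}

# 1:1 Langmuir shape (unit R_max) for one trace: 0 in baseline,
# (c/(Kd+c)) (1 - e^{-(kon c + koff)(t - t0)}) in association, exponential
# koff decay from the association end value in dissociation.
.bli_shape <- function(d, kon, koff) {
  cc <- d$conc[1]
  kd <- koff / kon
  s <- numeric(nrow(d))
  ia <- d$phase == "association"
  id <- d$phase == "dissociation"
  t0 <- if (any(ia)) min(d$time[ia]) else 0
  # association ends where dissociation starts (the association phase grid
  # does not necessarily contain the switch time itself)
  te <- if (any(id)) min(d$time[id]) else if (any(ia)) max(d$time[ia]) else t0
  kobs <- kon * cc + koff
  req <- cc / (kd + cc)
  if (any(ia)) s[ia] <- req * (1 - exp(-kobs * (d$time[ia] - t0)))
  if (any(id)) {
    r_end <- req * (1 - exp(-kobs * (te - t0)))
    s[id] <- r_end * exp(-koff * (d$time[id] - te))
  }
  s
}

#' Global 1:1 kinetic fit of multi-concentration BLI sensorgrams
#'
#' Traces recorded at different analyte concentrations are fitted
#' simultaneously with shared (`k_on`, `k_off`, `R_max`) and a per-trace
#' constant offset (nuisance, absorbing immobilization differences):
#' association `R(t) = R_eq (1 - e^{-(k_on c + k_off) t})` with
#' `R_eq = R_max c / (K_d + c)`, dissociation mono-exponential with `k_off`,
#' and `K_d = k_off / k_on`. For fixed rate constants the model is linear in
#' `R_max` and the offsets, so those are profiled out and a 2-D optimization
#' over `log10(k_on)`, `log10(k_off)` remains. `k_off` is started from a
#' log-linear regression on the dissociation phase of the highest
#' concentration and `k_on` from a coarse grid scan.
#'
#' @param table an [assay_table] of kind `sensorgram`, preferably after
#'   [bli_preprocess].
#' @param fit_offsets fit a per-trace constant offset (default TRUE).
#' @param koff_min lower bound for `k_off` (1/s); a fit ending at this bound
#'   is flagged `koff_at_bound` (slow-dissociator regime).
#' @return a `bli_fit` with `kon` (1/M/s), `koff` (1/s), `kd = koff/kon` (M),
#'   `rmax`, `offsets`, `sse`, `converged`.
#' @export
bli_global_fit <- function(table, fit_offsets = TRUE, koff_min = 1e-7) {
  sgs <- split_sensorgrams(table)
  if (length(unique(vapply(sgs, function(d) d$conc[1], numeric(1)))) < 3) {
    stop_badarg("need sensorgrams at >= 3 analyte concentrations")
  }
  ntr <- length(sgs)
  nobs <- vapply(sgs, nrow, integer(1))
  y <- unlist(lapply(sgs, `[[`, "response"), use.names = FALSE)
  trace_id <- rep(seq_len(ntr), nobs)

  lin_sse <- function(lkon, lkoff) {
    kon <- 10^lkon; koff <- 10^lkoff
    s <- unlist(lapply(sgs, .bli_shape, kon = kon, koff = koff),
                use.names = FALSE)
    if (fit_offsets) {
      X <- cbind(s, stats::model.matrix(~ 0 + factor(trace_id)))
    } else {
      X <- cbind(s)
    }
    ft <- stats::.lm.fit(X, y)
    r <- y - X %*% ft$coefficients
    list(sse = sum(r * r), coef = ft$coefficients)
  }

  # k_off start: log-linear decay of the top-concentration dissociation phase
  top <- sgs[[which.max(vapply(sgs, function(d) d$conc[1], numeric(1)))]]
  dis <- top[top$phase == "dissociation" & top$response > 0, , drop = FALSE]
  lkoff0 <- if (nrow(dis) >= 5) {
    sl <- stats::coef(stats::lm(log(dis$response) ~ dis$time))[2]
    log10(max(-unname(sl), 1e-6))
  } else -3
  lkon_grid <- seq(3, 7, by = 0.5)
  sse_g <- vapply(lkon_grid, function(lk) lin_sse(lk, lkoff0)$sse, numeric(1))
  start <- c(lkon_grid[which.min(sse_g)], lkoff0)

  obj <- function(p) {
    if (p[2] < log10(koff_min)) p[2] <- log10(koff_min)
    lin_sse(p[1], p[2])$sse
  }
  # Nelder-Mead with restarts: re-simplexing at the found optimum tightens
  # the final contraction considerably
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  for (r in 1:3) {
    opt2 <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
    if (opt2$value >= opt$value * (1 - 1e-12)) { opt <- opt2; break }
    opt <- opt2
  }

  lkon <- opt$par[1]
  lkoff <- max(opt$par[2], log10(koff_min))
  sol <- lin_sse(lkon, lkoff)
  koff_at_bound <- lkoff <= log10(koff_min) + 1e-9
  if (koff_at_bound) {
    warning("k_off hit its lower bound (slow-dissociator regime)",
            call. = FALSE)
  }
  kon <- 10^lkon; koff <- 10^lkoff
  structure(list(kon = kon, koff = koff, kd = koff / kon,
                 rmax = unname(sol$coef[1]),
                 offsets = if (fit_offsets) {
                   stats::setNames(unname(sol$coef[-1]), names(sgs))
                 } else stats::setNames(rep(0, ntr), names(sgs)),
                 sse = sol$sse, n = length(y),
                 koff_at_bound = koff_at_bound,
                 converged = opt$convergence == 0),
            class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  cat(sprintf(
    "<bli_fit 1:1 global: k_on=%.4g 1/M/s, k_off=%.4g 1/s, K_d=%.4g nM, R_max=%.4g, sse=%.4g, converged=%s>\n",
    x$kon, x$koff, x$kd / 1e-9, x$rmax, x$sse, x$converged))
  invisible(x)
}

#' @export
as_report.bli_fit <- function(fit) {
  list(model = "bli_1to1_global", kon = fit$kon, koff = fit$koff, kd = fit$kd,
       rmax = fit$rmax, offsets = as.list(fit$offsets), sse = fit$sse,
       n = fit$n, koff_at_bound = fit$koff_at_bound, converged = fit$converged)
}
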