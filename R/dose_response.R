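# EC50 dose-response fitting with Monte Carlo confidence intervals.
#
# Per-concentration labeling rates (k_app or initial slopes) are fitted
# against the complementing-peptide concentration with a sigmoidal
# dose-response model of fixed Hill slope 1. Two algebraically equivalent
# parameterizations are supported:
#
#   log-sigmoid:  k_app(X) = k_max / (1 + 10^(log10 EC50 - log10 X))   (Bottom = 0)
#   hyperbolic:   Y = Bottom + X (Top - Bottom) / (EC50 + X)
#
# For Bottom = 0 the two are identical: k_max/(1 + EC50/X) = k_max X/(EC50+X).
# The fit profiles the amplitude parameters (which enter linearly) out of the
# least-squares problem and optimizes the 1-D profile over log10(EC50) — this
# keeps EC50 positive, is scale-equivariant, and is fast enough for the
# N = 1000 Monte Carlo refits.

#' Dose-response model evaluators (fixed Hill slope 1)
#'
#' `ec50_log_sigmoid()` evaluates `k_max / (1 + 10^(log10 EC50 - log10 X))`;
#' `ec50_hyperbolic()` evaluates `Bottom + X (Top - Bottom)/(EC50 + X)`. The
#' two agree identically when `Bottom = 0`.
#'
#' @param conc concentrations X, M (> 0).
#' @param ec50 half-maximal concentration, M.
#' @param k_max,top rate (or response) at saturating concentration.
#' @param bottom response at zero concentration.
#' @return model values, same length as `conc`.
#' @export
ec50_log_sigmoid <- function(conc, ec50, k_max) {
  check_scalar(ec50, "ec50", positive = TRUE)
  k_max / (1 + 10^(log10(ec50) - log10(conc)))
}

#' @rdname ec50_log_sigmoid
#' @export
ec50_hyperbolic <- function(conc, ec50, top, bottom = 0) {
  check_scalar(ec50, "ec50", positive = TRUE)
  bottom + conc * (top - bottom) / (ec50 + conc)
}

#' Assemble dose-response points
#'
#' @param conc peptide concentrations, M (> 0).
#' @param rate per-concentration rate: `k_app` (1/M/s) or initial slope
#'   (mP/s), one ordinate kind per dataset.
#' @param sd optional per-point SD of the rate (used as the Monte Carlo noise
#'   scale when provided).
#' @param ordinate which ordinate the rates are (`"k_app"` or `"slope"`).
#' @return a data frame of class `dose_response_points`.
#' @export
dose_response_points <- function(conc, rate, sd = NULL,
                                 ordinate = c("k_app", "slope")) {
  ordinate <- match.arg(ordinate)
  if (any(conc <= 0)) stop_badarg("concentrations must be > 0")
  stopifnot(length(conc) == length(rate))
  out <- data.frame(conc = as.numeric(conc), rate = as.numeric(rate))
  out$sd <- if (is.null(sd)) NA_real_ else as.numeric(sd)
  structure(out, ordinate = ordinate,
            class = c("dose_response_points", "data.frame"))
}

# Profile least squares over l = log10(EC50). Given l, the amplitudes solve a
# linear LS problem; returns the best (l, amplitudes, sse). `grid_n` coarse
# evaluations bracket the optimum for stats::optimize.
.profile_dr_fit <- function(x, y, form, grid_pad = 3, grid_n = 61) {
  lx <- log10(x)
  lo <- min(lx) - grid_pad
  hi <- max(lx) + grid_pad
  amp_sse <- function(l) {
    g <- x / (10^l + x)
    if (form == "hyperbolic") {
      X <- cbind(1 - g, g)
      cf <- stats::.lm.fit(X, y)$coefficients
      r <- y - X %*% cf
      list(sse = sum(r * r), bottom = cf[1], top = cf[2])
    } else {
      denom <- sum(g * g)
      k <- if (denom > 0) sum(y * g) / denom else 0
      r <- y - k * g
      list(sse = sum(r * r), bottom = 0, top = k)
    }
  }
  grid <- seq(lo, hi, length.out = grid_n)
  sse_g <- vapply(grid, function(l) amp_sse(l)$sse, numeric(1))
  i <- which.min(sse_g)
  bl <- grid[max(1L, i - 1L)]
  bu <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(function(l) amp_sse(l)$sse, c(bl, bu), tol = 1e-10)
  l_hat <- opt$minimum
  a <- amp_sse(l_hat)
  at_boundary <- i == 1L || i == grid_n
  list(l = l_hat, ec50 = 10^l_hat, top = unname(a$top),
       bottom = unname(a$bottom), sse = a$sse,
       fitted = a$bottom + (a$top - a$bottom) * x / (10^l_hat + x),
       at_boundary = at_boundary)
}

#' Fit the EC50 dose-response model (fixed Hill slope 1)
#'
#' @param points a [dose_response_points] data frame (or any data frame with
#'   `conc` and `rate` columns).
#' @param form `"log_sigmoid"` (Bottom fixed at 0, parameters `k_max` and
#'   `log10 EC50`) or `"hyperbolic"` (`Top`, `Bottom`, `EC50`). The forms
#'   agree exactly when Bottom = 0.
#' @return a `dose_response_fit` with `ec50` (M), `k_max` (Top), `bottom`,
#'   `sse`, `residual_sd`, `fitted`, `form`, `range_warning` (TRUE when the
#'   fitted EC50 lies more than 10x outside the tested concentration range),
#'   `converged`.
#' @export
fit_ec50 <- function(points, form = c("log_sigmoid", "hyperbolic")) {
  form <- match.arg(form)
  x <- points$conc
  y <- points$rate
  if (any(x <= 0)) stop_badarg("concentrations must be > 0")
  if (length(unique(x)) < 3) stop_badarg("need at least 3 distinct concentrations")
  if (diff(range(y)) == 0) {
    stop_badarg("all rates equal: EC50 is not identifiable")
  }
  pf <- .profile_dr_fit(x, y, form)
  p <- if (form == "hyperbolic") 3L else 2L
  dof <- max(length(y) - p, 1L)
  range_warning <- pf$ec50 > 10 * max(x) || pf$ec50 < min(x) / 10
  if (range_warning) {
    warning("fitted EC50 (", signif(pf$ec50, 4),
            " M) lies > 10x outside the tested concentration range",
            call. = FALSE)
  }
  structure(list(ec50 = pf$ec50, k_max = pf$top, bottom = pf$bottom,
                 sse = pf$sse, residual_sd = sqrt(pf$sse / dof),
                 fitted = pf$fitted, form = form, n = length(y),
                 conc = x, rate = y,
                 rate_sd = points$sd %||% rep(NA_real_, length(y)),
                 ordinate = attr(points, "ordinate") %||% "k_app",
                 range_warning = range_warning,
                 converged = !pf$at_boundary,
                 ci = c(NA_real_, NA_real_), n_mc = 0L, discard_frac = NA_real_,
                 mc_samples = numeric(0)),
            class = "dose_response_fit")
}

#' Monte Carlo confidence interval for a fitted EC50
#'
#' `n` synthetic replicate datasets are formed by adding Gaussian noise to the
#' fitted curve — parametrically, with scale equal to the per-point rate SD
#' when provided for every point, otherwise the residual SD of the fit — and
#' each is refitted. The `discard_frac` fraction of refits with the highest
#' refit SSE is discarded and the confidence interval is the percentile
#' interval of the surviving EC50 estimates. Defaults follow the analysis
#' convention of N = 1000 samples with the 5% worst fits discarded. The draw
#' is deterministic under `seed`.
#'
#' @param fit a `dose_response_fit` from [fit_ec50].
#' @param points the points the fit was computed from; defaults to those
#'   stored on the fit.
#' @param n number of Monte Carlo replicates.
#' @param discard_frac fraction of worst (highest-SSE) refits to discard.
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return the fit, with `ci`, `mc_samples`, `n_mc`, `discard_frac` filled in.
#' @export
monte_carlo_ci <- function(fit, points = NULL, n = 1000, discard_frac = 0.05,
                           seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!isTRUE(fit$converged)) stop_badarg("Monte Carlo CI requires a converged fit")
  x <- points$conc %||% fit$conc
  sds <- if (!is.null(points) && all(is.finite(points$sd %||% NA))) {
    points$sd
  } else if (all(is.finite(fit$rate_sd))) {
    fit$rate_sd
  } else {
    rep(fit$residual_sd, length(x))
  }
  mu <- fit$fitted
  samples <- numeric(n)
  sses <- numeric(n)
  ok <- logical(n)
  with_seed(seed, {
    for (b in seq_len(n)) {
      yb <- mu + stats::rnorm(length(mu), 0, sds)
      pb <- tryCatch(.profile_dr_fit(x, yb, fit$form), error = function(e) NULL)
      if (is.null(pb) || !is.finite(pb$ec50) || pb$at_boundary) {
        ok[b] <- FALSE
      } else {
        ok[b] <- TRUE
        samples[b] <- pb$ec50
        sses[b] <- pb$sse
      }
    }
  })
  if (mean(!ok) > 0.2) {
    stop_badarg("Monte Carlo refits unstable: ",
                round(100 * mean(!ok)), "% of refits failed")
  }
  samples <- samples[ok]
  sses <- sses[ok]
  keep <- sses <= stats::quantile(sses, 1 - discard_frac, type = 7)
  surv <- samples[keep]
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(surv, c(alpha, 1 - alpha), type = 7))
  fit$ci <- ci
  fit$mc_samples <- surv
  fit$n_mc <- as.integer(n)
  fit$discard_frac <- discard_frac
  fit
}

#' Fold change between two EC50 (or K_d) values
#'
#' @param ec50_ref reference value, M (the larger/weaker-affinity one when
#'   reporting improvements).
#' @param ec50_new comparison value, M.
#' @return `ec50_ref / ec50_new` (dimensionless).
#' @export
fold_change <- function(ec50_ref, ec50_new) {
  check_scalar(ec50_ref, "ec50_ref", positive = TRUE)
  check_scalar(ec50_new, "ec50_new", positive = TRUE)
  ec50_ref / ec50_new
}

#' Report a fold change the way results sections phrase it
#'
#' Rounds to the nearest integer fold and renders small folds as words
#' ("twofold" ... "tenfold") and larger ones as "29-fold".
#'
#' @param fold numeric fold change.
#' @return character, e.g. `"fivefold"`, `"29-fold"`.
#' @export
format_fold <- function(fold) {
  k <- round(fold)
  words <- c("onefold", "twofold", "threefold", "fourfold", "fivefold",
             "sixfold", "sevenfold", "eightfold", "ninefold", "tenfold")
  ifelse(k >= 1 & k <= 10, words[pmax(k, 1)], paste0(k, "-fold"))
}

#' Fit per-concentration kinetics and aggregate into an EC50 estimate
#'
#' The full dose-response pipeline: average replicates of an `fp_timecourse`
#' table, fit each concentration's time course (second-order model with linear
#' fallback), build dose-response points (using `k_app` when every
#' second-order fit converged and plateaued, otherwise initial slopes — mixed
#' ordinates are never used), fit the EC50 and attach a Monte Carlo CI.
#'
#' @param table an `fp_timecourse` [assay_table] spanning a dilution series.
#' @param a0,b0 reagent concentrations (M), defaulting to the table metadata.
#' @param dead_time dead time (s) passed to the kinetic fits (default: value
#'   recorded on the table).
#' @param form dose-response parameterization, see [fit_ec50].
#' @param n_mc,discard_frac,seed Monte Carlo CI settings, see [monte_carlo_ci].
#' @return a `dose_response_fit` with the per-concentration `kinetic_fit`s
#'   attached as `kinetics`.
#' @export
ec50_pipeline <- function(table, a0 = NULL, b0 = NULL, dead_time = NULL,
                          form = "log_sigmoid", n_mc = 1000,
                          discard_frac = 0.05, seed = 1) {
  tcs <- average_replicates(table, a0 = a0, b0 = b0)
  fits <- lapply(tcs, fit_kinetics, dead_time = dead_time)
  models <- vapply(fits, `[[`, character(1), "model")
  concs <- vapply(tcs, `[[`, numeric(1), "conc")
  if (all(models == "second_order")) {
    pts <- dose_response_points(concs, vapply(fits, `[[`, numeric(1), "k_app"),
                                ordinate = "k_app")
  } else {
    pts <- dose_response_points(
      concs, mapply(initial_slope, fits, tcs), ordinate = "slope")
  }
  fit <- fit_ec50(pts, form = form)
  if (n_mc > 0) {
    fit <- monte_carlo_ci(fit, pts, n = n_mc, discard_frac = discard_frac,
                          seed = seed)
  }
  fit$kinetics <- fits
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit (%s): EC50=%.4g nM, k_max/Top=%.4g, Bottom=%.4g, n=%d>\n",
    x$form, x$ec50 / 1e-9, x$k_max, x$bottom, x$n))
  if (x$n_mc > 0) {
    cat(sprintf("  95%% Monte Carlo CI: (%.4g - %.4g) nM  [N=%d, %g%% worst discarded]\n",
                x$ci[1] / 1e-9, x$ci[2] / 1e-9, x$n_mc, 100 * x$discard_frac))
  }
  invisible(x)
}

#' @export
as_report.dose_response_fit <- function(fit) {
  list(model = "dose_response", form = fit$form,
       ec50 = fit$ec50, ec50_ci_low = fit$ci[1], ec50_ci_high = fit$ci[2],
       kmax = fit$k_max, bottom = fit$bottom, ordinate = fit$ordinate,
       sse = fit$sse, residual_sd = fit$residual_sd, n = fit$n,
       n_mc = fit$n_mc, discard_frac = fit$discard_frac,
       range_warning = fit$range_warning, converged = fit$converged)
}

#' @export
as_report.kinetic_fit <- function(fit) {
  list(model = fit$model, k_app = fit$k_app, fp_free = fit$fp_free,
       fp_bound = fit$fp_bound, slope0 = fit$slope0,
       dead_time = fit$dead_time, sse = fit$sse, converged = fit$converged,
       n = fit$n)
}
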