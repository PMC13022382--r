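# Second-order labeling kinetics.
#
# The covalent labeling of the reconstituted split tag with a chloroalkane-dye
# substrate A by protein B follows an irreversible bimolecular reaction
# A + B -> P with rate constant k_app. With fluorescence polarization as the
# readout (FP_free for free dye, FP_bound for the covalent adduct), the closed
# form for unequal starting concentrations [A]0 != [B]0 is
#
#   FP(t) = FP_bound + (FP_free - FP_bound)/[A]0 *
#           [A]0([A]0 - [B]0) e^{([A]0-[B]0) k t} /
#           ([A]0 e^{([A]0-[B]0) k t} - [B]0)
#
# i.e. FP(t) = FP_bound + (FP_free - FP_bound) * A(t)/[A]0 with A(t) the
# remaining substrate. At [A]0 = [B]0 the expression degenerates to the
# analytic limit A(t)/[A]0 = 1/(1 + [A]0 k t).

#' Evaluate the second-order labeling model
#'
#' Numerically stable evaluation of the bimolecular FP labeling curve. The
#' exponential is rearranged so its argument is always non-positive, which
#' avoids overflow when `a0 > b0` at long times. When `a0` and `b0` agree
#' within `equal_tol` relative, the equal-concentration limit
#' `FP_bound + (FP_free - FP_bound)/(1 + a0 k t)` is used to avoid 0/0.
#'
#' @param t time(s) in seconds (non-negative).
#' @param k_app apparent second-order rate constant, 1/M/s.
#' @param fp_free,fp_bound FP of the free and bound fluorophore, mP.
#' @param a0 substrate (dye) concentration at t = 0, M.
#' @param b0 protein concentration at t = 0, M.
#' @param equal_tol relative tolerance below which `a0` and `b0` are treated
#'   as equal.
#' @return FP values, same length as `t`.
#' @export
fp_second_order <- function(t, k_app, fp_free, fp_bound, a0, b0,
                            equal_tol = 1e-6) {
  check_scalar(a0, "a0", positive = TRUE)
  check_scalar(b0, "b0", positive = TRUE)
  check_scalar(k_app, "k_app", nonneg = TRUE)
  if (abs(a0 - b0) <= equal_tol * a0) {
    frac <- 1 / (1 + a0 * k_app * t)
  } else {
    d <- a0 - b0  # exponent (a0-b0) k t
    # remaining fraction A(t)/a0 = (a0-b0) E / (a0 E - b0), E = exp(d k t)
    if (d < 0) {
      e <- exp(d * k_app * t)               # decays, safe
      frac <- d * e / (a0 * e - b0)
    } else {
      e <- exp(-d * k_app * t)              # decays, safe
      frac <- d / (a0 - b0 * e)
    }
  }
  fp_bound + (fp_free - fp_bound) * frac
}

#' Construct a labeling time course
#'
#' Holds one (replicate-averaged) FP-vs-time trace together with the reagent
#' concentrations needed by the kinetic model, the complementing-peptide
#' concentration of the condition, and the dead time already known for the
#' trace (the delay between substrate addition and the first recorded point;
#' simulated data record the dead time the generator applied).
#'
#' @param t times in seconds, non-negative and strictly increasing.
#' @param fp FP values in mP.
#' @param a0 substrate concentration at t = 0, M.
#' @param b0 protein concentration at t = 0, M.
#' @param conc condition (peptide) concentration, M, or `NA`.
#' @param dead_time dead time in seconds associated with the trace.
#' @param fp_sd optional per-time SD across replicates (diagnostic only).
#' @return an object of class `time_course`.
#' @export
time_course <- function(t, fp, a0, b0, conc = NA_real_, dead_time = 0,
                        fp_sd = NULL) {
  stopifnot(length(t) == length(fp))
  if (any(t < 0)) stop_badarg("times must be non-negative")
  if (any(diff(t) <= 0)) stop_badarg("times must be strictly increasing")
  check_scalar(a0, "a0", positive = TRUE)
  check_scalar(b0, "b0", positive = TRUE)
  check_scalar(dead_time, "dead_time", nonneg = TRUE)
  structure(list(t = as.numeric(t), fp = as.numeric(fp), a0 = a0, b0 = b0,
                 conc = conc, dead_time = dead_time, fp_sd = fp_sd),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf(
    "<time_course: %d points, t in [%g, %g] s, a0=%.3g M, b0=%.3g M, conc=%.3g M>\n",
    length(x$t), min(x$t), max(x$t), x$a0, x$b0, x$conc))
  invisible(x)
}

#' Average replicate series of an FP time-course table into time courses
#'
#' Replicate traces sharing a condition are averaged point-wise before fitting
#' (the per-time SD across replicates is retained for diagnostics). The input
#' is an `fp_timecourse` [assay_table]; reagent concentrations are taken from
#' its metadata unless given explicitly.
#'
#' @param table an [assay_table] of kind `fp_timecourse`.
#' @param a0,b0 reagent concentrations (M); default from `meta$a0`, `meta$b0`.
#' @return named list of [time_course] objects, one per distinct condition,
#'   sorted by decreasing concentration.
#' @export
average_replicates <- function(table, a0 = NULL, b0 = NULL) {
  stopifnot(inherits(table, "assay_table"), assay_kind(table) == "fp_timecourse")
  meta <- assay_meta(table)
  a0 <- a0 %||% meta$a0
  b0 <- b0 %||% meta$b0
  dead_time <- meta$dead_time %||% 0
  if (is.null(a0) || is.null(b0)) {
    stop_badarg("a0/b0 not found in table metadata; pass them explicitly")
  }
  concs <- sort(unique(table$conc), decreasing = TRUE)
  out <- lapply(concs, function(cc) {
    sub <- table[table$conc == cc, , drop = FALSE]
    m <- tapply(sub$fp, sub$time, mean)
    s <- tapply(sub$fp, sub$time, stats::sd)
    tt <- as.numeric(names(m))
    o <- order(tt)
    time_course(tt[o], as.numeric(m)[o], a0 = a0, b0 = b0, conc = cc,
                dead_time = dead_time, fp_sd = as.numeric(s)[o])
  })
  names(out) <- sprintf("%.6g nM", concs / 1e-9)
  out
}

#' Fit the second-order labeling model to a time course
#'
#' Nonlinear least squares over (`k_app`, `fp_free`, `fp_bound`) of the
#' bimolecular FP model evaluated at `t + dead_time`. `k_app` is fitted as
#' `log10(k_app)` to keep it positive; start values come from a coarse
#' log-grid scan over 1e2-1e7 1/M/s with `fp_free`/`fp_bound` initialized at
#' the first/last observed values. Optimizer failure is reported via
#' `converged = FALSE` (with the best grid-scan parameters), never silently.
#'
#' @param tc a [time_course].
#' @param dead_time dead time in seconds added to all times before evaluating
#'   the model; defaults to the dead time stored on the time course. Fixed, not
#'   a free fit parameter (a free offset is weakly identified against `k_app`).
#' @return a `kinetic_fit` with fields `model` (`"second_order"`), `k_app`,
#'   `fp_free`, `fp_bound`, `slope0` (initial slope of the fitted curve, mP/s),
#'   `dead_time`, `sse`, `converged`.
#' @export
fit_second_order <- function(tc, dead_time = NULL) {
  stopifnot(inherits(tc, "time_course"))
  if (length(tc$t) < 5) stop_badarg("need at least 5 time points")
  dead_time <- dead_time %||% tc$dead_time
  tt <- tc$t + dead_time
  y <- tc$fp
  a0 <- tc$a0; b0 <- tc$b0

  sse_at <- function(lk, ff, fb) {
    sum((y - fp_second_order(tt, 10^lk, ff, fb, a0, b0))^2)
  }
  ff0 <- y[1]; fb0 <- y[length(y)]
  grid <- seq(2, 7, by = 0.25)
  sse_grid <- vapply(grid, sse_at, numeric(1), ff = ff0, fb = fb0)
  lk0 <- grid[which.min(sse_grid)]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fp_second_order(tt, 10^lk, ff, fb, a0, b0),
      start = list(lk = lk0, ff = ff0, fb = fb0),
      lower = c(lk = -3, ff = -Inf, fb = -Inf),
      upper = c(lk = 10, ff = Inf, fb = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    p <- c(lk = lk0, ff = ff0, fb = fb0)
    converged <- FALSE
    sse <- sse_at(p["lk"], p["ff"], p["fb"])
  } else {
    p <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    sse <- sum(stats::resid(fit)^2)
  }
  k_app <- unname(10^p["lk"])
  fp_free <- unname(p["ff"]); fp_bound <- unname(p["fb"])
  structure(list(model = "second_order", k_app = k_app, fp_free = fp_free,
                 fp_bound = fp_bound,
                 slope0 = k_app * b0 * (fp_bound - fp_free),
                 dead_time = dead_time, sse = sse, converged = converged,
                 n = length(y)),
            class = "kinetic_fit")
}

#' Fit a linear model to a time course
#'
#' Fallback for reactions that do not approach plateau within the measured
#' window, where only the initial labeling speed is identifiable.
#'
#' @param tc a [time_course].
#' @return a `kinetic_fit` with `model = "linear"`, `slope0` the fitted line
#'   slope (mP/s) and `fp_free` its intercept.
#' @export
fit_linear <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  fit <- stats::lm(fp ~ t, data = list(t = tc$t, fp = tc$fp))
  co <- stats::coef(fit)
  structure(list(model = "linear", k_app = NA_real_,
                 fp_free = unname(co[1]), fp_bound = NA_real_,
                 slope0 = unname(co[2]), dead_time = tc$dead_time,
                 sse = sum(stats::resid(fit)^2), converged = TRUE,
                 n = length(tc$t)),
            class = "kinetic_fit")
}

#' Choose between the second-order model and the linear fallback
#'
#' Conditions whose reactions do not plateau within the measurement window are
#' fitted linearly. The decision uses the reaction completion predicted by the
#' second-order fit at the final time point,
#' `(FP(t_end) - fp_free)/(fp_bound - fp_free)`: completion below `threshold`
#' (default 20%, keeping the trace in the near-linear regime) selects
#' `"linear"`; completion exactly at the threshold selects `"second_order"`
#' (inclusive). A non-converged second-order fit also selects `"linear"`.
#'
#' @param tc the fitted [time_course].
#' @param fit the `kinetic_fit` from [fit_second_order].
#' @param threshold completion fraction below which the linear model is used.
#' @return `"second_order"` or `"linear"`.
#' @export
choose_model <- function(tc, fit, threshold = 0.2) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!isTRUE(fit$converged)) return("linear")
  t_end <- max(tc$t) + fit$dead_time
  span <- fit$fp_bound - fit$fp_free
  if (!is.finite(span) || span == 0) return("linear")
  pred_end <- fp_second_order(t_end, fit$k_app, fit$fp_free, fit$fp_bound,
                              tc$a0, tc$b0)
  completion <- (pred_end - fit$fp_free) / span
  if (completion < threshold) "linear" else "second_order"
}

#' Fit a time course, selecting the model automatically
#'
#' Convenience wrapper: fits the second-order model, applies [choose_model],
#' and refits linearly when indicated.
#'
#' @inheritParams fit_second_order
#' @param threshold completion threshold passed to [choose_model].
#' @return a `kinetic_fit`.
#' @export
fit_kinetics <- function(tc, dead_time = NULL, threshold = 0.2) {
  fit <- fit_second_order(tc, dead_time = dead_time)
  if (choose_model(tc, fit, threshold) == "linear") fit_linear(tc) else fit
}

#' Initial slope of a fitted labeling curve
#'
#' For the second-order model this is the analytic derivative of the fitted
#' curve at t = 0: since dA/dt(0) = -k_app a0 b0, the FP slope is
#' `k_app * b0 * (fp_bound - fp_free)` (mP/s). For the linear fallback it is
#' the fitted line slope.
#'
#' @param fit a `kinetic_fit`.
#' @param tc the corresponding [time_course] (unused for the linear model).
#' @return initial slope in mP/s.
#' @export
initial_slope <- function(fit, tc = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (fit$model == "linear") return(fit$slope0)
  b0 <- if (!is.null(tc)) tc$b0 else fit$slope0 / (fit$k_app * (fit$fp_bound - fit$fp_free))
  fit$k_app * b0 * (fit$fp_bound - fit$fp_free)
}

#' Fit the pseudo-first-order background labeling model
#'
#' Residual labeling of the large fragment alone (no peptide, protein in large
#' excess over substrate) follows a one-phase association
#' `y(t) = y0 + (plateau - y0) (1 - exp(-k_obs t))`; the labeling half-time is
#' `t_half = ln(2)/k_obs`. When the curve shows no appreciable progress over
#' the window (`k_obs * t_end < 0.01`), `t_half` is effectively unbounded and
#' the fit is flagged.
#'
#' @param tc a [time_course] (at least 5 points).
#' @return a `background_fit` with `k_obs` (1/s), `t_half` (s), `plateau`,
#'   `y0`, `sse`, `converged`, `unbounded`.
#' @export
fit_background <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (length(tc$t) < 5) stop_badarg("need at least 5 time points")
  tt <- tc$t; y <- tc$fp
  y0s <- y[1]; pls <- y[length(y)]
  k0 <- 1 / max(mean(tt), .Machine$double.eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (plateau - y0) * (1 - exp(-exp(lk) * tt)),
      start = list(y0 = y0s, plateau = pls, lk = log(k0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(k_obs = k0, plateau = pls, y0 = y0s,
                sse = sum((y - mean(y))^2), converged = FALSE)
  } else {
    p <- stats::coef(fit)
    out <- list(k_obs = unname(exp(p["lk"])), plateau = unname(p["plateau"]),
                y0 = unname(p["y0"]), sse = sum(stats::resid(fit)^2),
                converged = isTRUE(fit$convInfo$isConv))
  }
  out$t_half <- log(2) / out$k_obs
  out$unbounded <- out$k_obs * max(tt) < 0.01 ||
    abs(out$plateau - out$y0) <= 1e-8 * max(abs(y), 1) ||
    !out$converged
  structure(out, class = "background_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$model == "second_order") {
    cat(sprintf(
      "<kinetic_fit second_order: k_app=%.4g 1/M/s, FP_free=%.4g, FP_bound=%.4g, s(t=0)=%.4g mP/s, sse=%.4g, converged=%s>\n",
      x$k_app, x$fp_free, x$fp_bound, x$slope0, x$sse, x$converged))
  } else {
    cat(sprintf("<kinetic_fit linear: slope=%.4g mP/s, intercept=%.4g, sse=%.4g>\n",
                x$slope0, x$fp_free, x$sse))
  }
  invisible(x)
}

#' @export
print.background_fit <- function(x, ...) {
  cat(sprintf(
    "<background_fit: k_obs=%.4g 1/s, t_half=%.4g s%s, converged=%s>\n",
    x$k_obs, x$t_half, if (x$unbounded) " (unbounded)" else "", x$converged))
  invisible(x)
}
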