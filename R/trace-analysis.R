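#' Analysis configuration
#'
#' Tuning knobs for kinetic-parameter extraction from an oxygen-uptake trace.
#'
#' @param smooth_window Samples for the centred moving average used by the
#'   induction-period detector only; slope fits always use raw samples.
#'   Default 5.
#' @param rate_window_frac Fraction of the relevant record used for the
#'   tangent-line slope fits in [detect_tau()]. Default 0.25.
#' @param eq2_window Fractional range of tau used for the integrated-rate-law
#'   regression and the inhibited-rate window, default `c(0.10, 0.80)`:
#'   the lower bound avoids the injection transient, the upper bound the
#'   logarithmic divergence as the antioxidant runs out.
#' @param tau_method `"tangent_intersection"` (default) or
#'   `"second_derivative"`.
#' @param class_thresholds Named list:
#'   `kinh_ratio_min` (default 100) - a compound with an induction period is
#'   an antioxidant when `kinh >= kinh_ratio_min * kp` (strong traps have
#'   `kinh` well above 100-fold `kp`);
#'   `retard_frac` (default 0.90) - without an induction period the compound
#'   is a retarder when `Rinh <= retard_frac * Rox1(control)`;
#'   `tau_slope_ratio_min` (default 2) - minimum ratio of post-inhibition to
#'   inhibited tangent slope for an induction period to be declared. Below
#'   it the trace has no real inflection, i.e. retardation: a retarder's
#'   apparent "late vs early" slope ratio stays close to 1 (it only creeps
#'   up as the compound is consumed), whereas even a faint genuine
#'   induction period gives a ratio of 3 or more before measurement
#'   curvature erodes it.
#' @param min_r2 Minimum r-squared for a trustworthy integrated-rate-law fit,
#'   default 0.99.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(smooth_window = 5L,
                            rate_window_frac = 0.25,
                            eq2_window = c(0.10, 0.80),
                            tau_method = c("tangent_intersection",
                                           "second_derivative"),
                            class_thresholds = list(kinh_ratio_min = 100,
                                                    retard_frac = 0.90,
                                                    tau_slope_ratio_min = 2),
                            min_r2 = 0.99) {
  tau_method <- match.arg(tau_method)
  stopifnot(length(eq2_window) == 2L)
  if (!(eq2_window[1] > 0 && eq2_window[2] < 1 &&
        eq2_window[1] < eq2_window[2]))
    stop_domain("eq2_window bounds must satisfy 0 < lower < upper < 1")
  if (rate_window_frac <= 0 || rate_window_frac >= 1)
    stop_domain("rate_window_frac must lie in (0, 1)")
  th <- class_thresholds
  if (any(unlist(th[c("kinh_ratio_min", "retard_frac",
                      "tau_slope_ratio_min")]) <= 0))
    stop_domain("class_thresholds must be positive")
  structure(list(smooth_window = as.integer(smooth_window),
                 rate_window_frac = rate_window_frac,
                 eq2_window = eq2_window, tau_method = tau_method,
                 class_thresholds = th, min_r2 = min_r2),
            class = "analysis_config")
}

#' Oxidation rate over a time window
#'
#' Least-squares slope of dissolved O2 against time over `window`, negated so
#' that a falling trace gives a positive uptake rate, and clipped at zero.
#' No smoothing is applied.
#'
#' @param trace An [ox_trace()].
#' @param window Length-2 numeric, time interval in s (must contain at least
#'   5 samples).
#' @return Rate, M s^-1 (>= 0).
#' @export
estimate_rate <- function(trace, window) {
  stopifnot(inherits(trace, "ox_trace"), length(window) == 2L)
  idx <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(idx) < 5L)
    stop_analysis(sprintf("rate window [%.1f, %.1f] s contains %d samples (need >= 5)",
                          window[1], window[2], sum(idx)))
  fit <- ls_line(trace$times[idx], trace$o2[idx])
  max(0, -fit$slope)
}

# Two-segment least-squares corner locator: index minimizing the summed SSE
# of one line fitted before and one after the breakpoint.
segment_corner <- function(t, y) {
  n <- length(t)
  lo <- 5L
  hi <- n - 5L
  cand <- seq(lo, hi, by = max(1L, (hi - lo) %/% 150L))
  sse <- vapply(cand, function(b) {
    f1 <- ls_line(t[1:b], y[1:b])
    f2 <- ls_line(t[b:n], y[b:n])
    sum((y[1:b] - (f1$intercept + f1$slope * t[1:b]))^2) +
      sum((y[b:n] - (f2$intercept + f2$slope * t[b:n]))^2)
  }, numeric(1))
  cand[which.min(sse)]
}

induction_estimate <- function(tau = NA_real_, method = NA_character_,
                               window = NULL, diagnostic = NULL) {
  structure(list(tau = tau, method = method, window = window,
                 diagnostic = diagnostic),
            class = "induction_estimate")
}

#' @export
print.induction_estimate <- function(x, ...) {
  if (is.na(x$tau)) {
    cat("No induction period detected")
    if (!is.null(x$diagnostic)) cat(" (", x$diagnostic, ")", sep = "")
    cat("\n")
  } else {
    cat(sprintf("Induction period tau = %.0f s (%.1f min), method: %s\n",
                x$tau, x$tau / 60, x$method))
  }
  invisible(x)
}

#' Detect the induction period of an inhibited trace
#'
#' Locates the inflection where the antioxidant is exhausted and oxidation
#' accelerates. The default tangent-intersection detector first finds the
#' corner of the post-injection record by two-segment least squares, then
#' fits a tangent to the early inhibited phase and one to the late
#' post-inhibition phase and intersects them; tau is the intersection
#' abscissa minus the injection time. The alternative second-derivative
#' detector takes the point of maximum downward curvature of the smoothed
#' trace. No induction period is declared (tau absent) when the two tangent
#' slopes differ by less than `tau_slope_ratio_min` - the signature of
#' retardation rather than inhibition - or when O2 is exhausted before any
#' inflection.
#'
#' @param trace An [ox_trace()] with an antioxidant injection time (a trace
#'   without one yields an absent estimate).
#' @param config An [analysis_config()].
#' @return An object of class `induction_estimate` with fields `tau` (s, or
#'   `NA`), `method`, `window` and `diagnostic`.
#' @export
detect_tau <- function(trace, config = analysis_config()) {
  stopifnot(inherits(trace, "ox_trace"), inherits(config, "analysis_config"))
  if (is.na(trace$t_aox))
    return(induction_estimate(diagnostic = "no antioxidant injection recorded"))

  t0 <- trace$t_aox
  idx <- trace$times >= t0
  t <- trace$times[idx]
  y <- moving_average(trace$o2[idx], config$smooth_window)
  n <- length(t)
  if (n < 20L)
    return(induction_estimate(diagnostic = "too few post-injection samples"))
  tend <- t[n]

  b <- segment_corner(t, y)
  t_corner <- t[b]
  tau0 <- t_corner - t0
  if (tau0 <= 0)
    return(induction_estimate(diagnostic = "no inflection located"))

  if (config$tau_method == "second_derivative") {
    d2 <- diff(y, differences = 2)
    # most negative curvature = sharpest downward bend; restrict to the
    # interior (edge samples carry smoothing artefacts, and the injection
    # transient bends the other way)
    k <- seq_along(d2)
    tmid <- t[k + 1L]
    ok <- tmid >= t0 + 0.05 * (tend - t0) & tmid <= tend - 0.05 * (tend - t0)
    if (!any(ok))
      return(induction_estimate(diagnostic = "record too short"))
    j <- k[ok][which.min(d2[ok])] + 1L
    tau <- t[j] - t0
    # still require a real slope contrast around the bend
    w1 <- t >= t0 + 0.05 * tau & t <= t0 + 0.5 * tau
    w2 <- t >= t[j] + 0.15 * (tend - t[j])
    if (sum(w1) >= 5 && sum(w2) >= 5) {
      s1 <- -ls_line(t[w1], y[w1])$slope
      s2 <- -ls_line(t[w2], y[w2])$slope
      ratio <- if (s1 > 0) s2 / s1 else Inf
      if (!is.finite(ratio) ||
          ratio < config$class_thresholds$tau_slope_ratio_min)
        return(induction_estimate(diagnostic = "no slope contrast (retardation)"))
    }
    return(induction_estimate(tau = tau, method = "second_derivative",
                              window = c(t0, tend)))
  }

  # Tangent intersection, iterated to self-consistency: the inhibited
  # tangent is fitted to the early part of the current induction estimate
  # (where the uptake curve is closest to linear), the steep tangent to the
  # post-corner record minus the bend region, and the intersection abscissa
  # becomes the next estimate.
  tau_hat <- tau0
  f1 <- f2 <- NULL
  for (k in 1:4) {
    w1 <- t >= t0 + 0.05 * tau_hat & t <= t0 + 0.35 * tau_hat
    post_len <- tend - (t0 + tau_hat)
    if (post_len <= 0)
      return(induction_estimate(diagnostic = "O2 exhausted before inflection"))
    w2 <- t >= t0 + tau_hat + 0.15 * post_len & t <= tend
    if (sum(w1) < 5 || sum(w2) < 5)
      return(induction_estimate(diagnostic = "O2 exhausted before inflection"))
    f1 <- ls_line(t[w1], y[w1])
    f2 <- ls_line(t[w2], y[w2])
    t_star <- (f1$intercept - f2$intercept) / (f2$slope - f1$slope)
    if (!is.finite(t_star) || t_star - t0 <= 0 || t_star > tend)
      return(induction_estimate(diagnostic = "no slope contrast (retardation)"))
    tau_hat <- t_star - t0
  }
  s1 <- -f1$slope
  s2 <- -f2$slope
  ratio <- if (s1 > 0) s2 / s1 else Inf
  if (!is.finite(ratio) || s2 <= 0 ||
      ratio < config$class_thresholds$tau_slope_ratio_min)
    return(induction_estimate(diagnostic = "no slope contrast (retardation)"))

  # The raw tangent intersection systematically undershoots tau: near the
  # end of the induction period the uptake curve diverges logarithmically
  # above the inhibited tangent, pulling the intersection early. Refine by
  # profiling the integrated-rate-law SSE over tau on the interior of the
  # induction window (exact for data generated by the law itself).
  up <- post_uptake(trace)
  tau <- refine_tau_eq2(up$t, up$U, tau_hat)
  induction_estimate(tau = tau, method = "tangent_intersection",
                     window = c(range(t[w1]), range(t[w2])))
}

# Cumulative O2 uptake since the antioxidant injection, with the initiation
# contribution removed when the trace metadata records it (same convention
# as fit_eq2).
post_uptake <- function(trace) {
  t0 <- trace$t_aox
  idx <- trace$times >= t0
  i0 <- which(idx)[1]
  tt <- trace$times[idx] - t0
  U <- trace$o2[i0] - trace$o2[idx]
  if (isTRUE(trace$meta$include_initiation_uptake) &&
      is.numeric(trace$meta$Ri))
    U <- U - trace$meta$Ri * tt
  list(t = tt, U = U)
}

# One-dimensional profile fit of the integrated inhibited rate law: for a
# fixed interior window the intercept/slope are profiled out by linear least
# squares and tau is chosen to minimize the SSE. Exact when the data follow
# the law; falls back to the supplied tau when the window is too thin.
refine_tau_eq2 <- function(tt, U, tau0) {
  idx <- tt >= 0.10 * tau0 & tt <= 0.75 * tau0
  if (sum(idx) < 8) return(tau0)
  tw <- tt[idx]
  Uw <- U[idx]
  sse <- function(tau) {
    x <- -log1p(-tw / tau)
    f <- ls_line(x, Uw)
    sum((Uw - (f$intercept + f$slope * x))^2)
  }
  lo <- max(tw) / 0.95
  hi <- 2.0 * tau0
  if (lo >= hi) return(tau0)
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-3)
  # a minimum hugging the upper bracket means the profile has no interior
  # optimum (the uptake is flatter than any integrated-law shape, as in
  # near-retardation); keep the tangent estimate in that case
  if (opt$minimum > 0.95 * hi) return(tau0)
  opt$minimum
}

#' Calibrate the initiation rate from a reference trace
#'
#' Measures the induction period of an antioxidant of known stoichiometry
#' (classically a 1 uM chromanol with n = 2) and returns
#' `Ri = n_ref * conc0 / tau`.
#'
#' @param reference_trace An [ox_trace()] of the reference antioxidant run.
#' @param n_ref Stoichiometric factor of the reference (> 0).
#' @param conc0 Reference concentration, M (> 0).
#' @param config An [analysis_config()].
#' @return Ri, M s^-1, with the measured tau attached as attribute `"tau"`.
#' @export
calibrate_ri <- function(reference_trace, n_ref = 2, conc0 = 1e-6,
                         config = analysis_config()) {
  est <- detect_tau(reference_trace, config)
  if (is.na(est$tau))
    stop(errorCondition(
      paste("no induction period on the reference trace;",
            "cannot calibrate Ri", est$diagnostic),
      class = c("oxikin_calibration_error", "oxikin_analysis_error",
                "oxikin_error")))
  ri <- initiation_rate(n_ref, conc0, est$tau)
  attr(ri, "tau") <- est$tau
  ri
}

#' Fit the integrated inhibited rate law to a trace
#'
#' Ordinary least squares of the cumulative O2 uptake
#' `U(t) = [O2]_(t_aox) - [O2]_t` against `-ln(1 - (t - t_aox)/tau)` over the
#' configured fractional window of the induction period; the slope equals
#' `kp * [LH] / kinh`, whence `kinh`. If the trace metadata records that the
#' simulated uptake includes the initiation term (`+Ri`), that contribution
#' `Ri * (t - t_aox)` is subtracted before regression - during strong
#' inhibition it is not negligible relative to the chain uptake. Fits with
#' r-squared below `min_r2` are flagged unreliable.
#'
#' @param trace An [ox_trace()] with an antioxidant injection time.
#' @param tau Induction period, s (> 0), e.g. from [detect_tau()].
#' @param params A [chain_params()] object (supplies `kp`, `LH0`).
#' @param config An [analysis_config()].
#' @return An object of class `eq2_fit` with fields `slope` (M), `intercept`
#'   (M), `r2`, `kinh` (M^-1 s^-1), `reliable`, `window` (s), and the
#'   regression data; supports `coef`, `predict`, `residuals`, `fitted`,
#'   `print` and `plot`.
#' @export
fit_eq2 <- function(trace, tau, params, config = analysis_config()) {
  stopifnot(inherits(trace, "ox_trace"), inherits(params, "chain_params"),
            inherits(config, "analysis_config"))
  check_positive(tau, "tau")
  if (is.na(trace$t_aox))
    stop_analysis("trace has no antioxidant injection time")
  t0 <- trace$t_aox
  lo <- t0 + config$eq2_window[1] * tau
  hi <- t0 + config$eq2_window[2] * tau
  idx <- trace$times >= lo & trace$times <= hi
  if (sum(idx) < 5L)
    stop_analysis("integrated-rate-law window contains fewer than 5 samples")
  i0 <- which(trace$times >= t0)[1]
  tt <- trace$times[idx] - t0
  U <- trace$o2[i0] - trace$o2[idx]
  subtract_ri <- isTRUE(trace$meta$include_initiation_uptake) &&
    is.numeric(trace$meta$Ri)
  if (subtract_ri) U <- U - trace$meta$Ri * tt
  x <- -log1p(-tt / tau)
  fit <- ls_line(x, U)
  if (fit$slope <= 0)
    stop_analysis("integrated-rate-law fit has non-positive slope")
  kinh <- params$kp * params$LH0 / fit$slope
  structure(list(slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
                 kinh = kinh, reliable = fit$r2 >= config$min_r2,
                 window = c(lo, hi), tau = tau, x = x, U = U,
                 initiation_subtracted = subtract_ri,
                 kp = params$kp, LH0 = params$LH0),
            class = "eq2_fit")
}

#' @export
print.eq2_fit <- function(x, ...) {
  cat("Integrated inhibited-rate-law fit\n")
  cat(sprintf("  slope = %.4g M, intercept = %.3g M, r2 = %.5f%s\n",
              x$slope, x$intercept, x$r2,
              if (x$reliable) "" else "  [UNRELIABLE]"))
  cat(sprintf("  kinh = kp*[LH]/slope = %.3g M^-1 s^-1\n", x$kinh))
  invisible(x)
}

#' @export
coef.eq2_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, kinh = object$kinh)
}

#' @rdname fit_eq2
#' @param object,x An `eq2_fit`.
#' @param t Times since antioxidant injection (s) at which to predict the
#'   uptake; defaults to the fitted window.
#' @param ... Unused.
#' @export
predict.eq2_fit <- function(object, t = NULL, ...) {
  xv <- if (is.null(t)) object$x else -log1p(-t / object$tau)
  object$intercept + object$slope * xv
}

#' @export
fitted.eq2_fit <- function(object, ...) predict(object)

#' @export
residuals.eq2_fit <- function(object, ...) object$U - fitted(object)

#' @export
plot.eq2_fit <- function(x, ...) {
  graphics::plot(x$x, x$U * 1e6, xlab = "-ln(1 - t/tau)",
                 ylab = "O2 uptake (uM)", ...)
  graphics::abline(a = x$intercept * 1e6, b = x$slope * 1e6, col = 2)
  invisible(x)
}

#' Classify kinetic behaviour
#'
#' Applies the standard taxonomy: a compound with a distinct induction period
#' and `kinh >= kinh_ratio_min * kp` is an `antioxidant`; one without an
#' induction period but a clearly slowed chain
#' (`Rinh <= retard_frac * Rox1(control)`) is a `retarder`; the designated
#' calibration standard is `reference`; anything else is `inactive`.
#' Boundary equalities resolve toward the stronger class.
#'
#' @param tau Induction period, s, or `NA` if none detected.
#' @param kinh Inhibition rate constant, M^-1 s^-1, or `NA`.
#' @param Rinh Inhibited/retarded rate of the test trace, M s^-1.
#' @param Rox1_control Uninhibited rate of the control, M s^-1 (required).
#' @param kp Propagation rate constant, M^-1 s^-1.
#' @param config An [analysis_config()].
#' @param reference Logical; `TRUE` for the calibration standard.
#' @return One of `"reference"`, `"antioxidant"`, `"retarder"`, `"inactive"`.
#' @export
classify_kinetics <- function(tau, kinh, Rinh, Rox1_control, kp = 41,
                              config = analysis_config(),
                              reference = FALSE) {
  if (is.null(Rox1_control) || !is.finite(Rox1_control))
    stop_analysis("control rate Rox1 is required for classification")
  if (isTRUE(reference)) return("reference")
  th <- config$class_thresholds
  if (!is.na(tau) && !is.na(kinh) && kinh >= th$kinh_ratio_min * kp)
    return("antioxidant")
  if (is.na(tau) && is.finite(Rinh) && Rinh <= th$retard_frac * Rox1_control)
    return("retarder")
  "inactive"
}

post_transient_window <- function(trace, skip_frac = 1 / 3) {
  t_end <- max(trace$times)
  len <- t_end - trace$t_init
  c(trace$t_init + skip_frac * len, t_end)
}

#' Full kinetic analysis of an inhibited-autoxidation trace
#'
#' Orchestrates the extraction pipeline and returns a report shaped like the
#' standard inhibited-autoxidation parameter table: uninhibited rate
#' (`Rox1`), inhibited/retarded rate (`Rinh`), post-inhibition rate (`Rox2`),
#' induction period (`tau`), initiation rate (`Ri`), kinetic chain lengths
#' (`nu_* = rate / Ri`), stoichiometric factor (`n_stoich`), inhibition rate
#' constant (`kinh`) and the behavioural classification. Every field that
#' cannot be computed for the trace at hand is left `NA`.
#'
#' Windows: the control `Rox1` is the slope over the final two thirds of the
#' post-initiation record (skipping the radical build-up transient). When an
#' induction period is found, `Rinh` is the slope over the `eq2_window`
#' fraction of it and `Rox2` the slope over the record after
#' `t_aox + 1.1 * tau`; without one, `Rinh` is the slope over the first half
#' of the post-injection record (the retarded process) and `Rox2` is absent.
#' All windows are recorded in `$provenance`.
#'
#' @param test [ox_trace()] to analyse.
#' @param control [ox_trace()] of the antioxidant-free run (same system).
#' @param reference Optional [ox_trace()] of the calibration standard used to
#'   measure `Ri` via [calibrate_ri()]; its stoichiometry and concentration
#'   are read from its metadata (fields `n_stoich`, `conc0`).
#' @param ri Optional known initiation rate, M s^-1; overrides `reference`.
#'   If neither is given, `params$Ri` is used.
#' @param params A [chain_params()] object.
#' @param config An [analysis_config()].
#' @param role `"test"` (default) or `"reference"` to mark the calibration
#'   standard itself.
#' @return An object of class `kinetic_report`; see also
#'   [kinetic_table()] for assembling several reports into one table.
#' @examples
#' \donttest{
#' set <- generate_experiment_set(seed = 1)
#' rep_tbg <- analyze_trace(set$TBG, control = set$control,
#'                          reference = set$PMHC, params = chain_params())
#' rep_tbg
#' }
#' @export
analyze_trace <- function(test, control, reference = NULL, ri = NULL,
                          params = chain_params(),
                          config = analysis_config(), role = "test") {
  stopifnot(inherits(test, "ox_trace"), inherits(control, "ox_trace"),
            inherits(params, "chain_params"))
  prov <- list(config = config, windows = list())

  ctrl_win <- post_transient_window(control)
  Rox1_ctrl <- estimate_rate(control, ctrl_win)
  prov$windows$Rox1_control <- ctrl_win

  if (!is.null(ri)) {
    Ri <- as.numeric(ri)
    prov$Ri_source <- "supplied"
  } else if (!is.null(reference)) {
    n_ref <- reference$meta$n_stoich
    c_ref <- reference$meta$conc0
    if (is.null(n_ref) || is.null(c_ref))
      stop_analysis("reference trace metadata lacks n_stoich/conc0")
    Ri <- as.numeric(calibrate_ri(reference, n_ref, c_ref, config))
    prov$Ri_source <- "reference trace"
  } else {
    Ri <- params$Ri
    prov$Ri_source <- "chain parameters"
  }

  t_end <- max(test$times)
  est <- detect_tau(test, config)
  tau <- est$tau

  if (!is.na(test$t_aox)) {
    pre_win <- c(test$t_init + 0.5 * (test$t_aox - test$t_init), test$t_aox)
    Rox1 <- tryCatch(estimate_rate(test, pre_win),
                     oxikin_analysis_error = function(e) NA_real_)
    prov$windows$Rox1 <- pre_win
    t0 <- test$t_aox
    if (!is.na(tau)) {
      inh_win <- c(t0 + config$eq2_window[1] * tau,
                   t0 + config$eq2_window[2] * tau)
      Rinh <- estimate_rate(test, inh_win)
      prov$windows$Rinh <- inh_win
      post_start <- t0 + 1.1 * tau
      Rox2 <- if (t_end - post_start > 0) {
        ox2_win <- c(post_start, t_end)
        prov$windows$Rox2 <- ox2_win
        tryCatch(estimate_rate(test, ox2_win),
                 oxikin_analysis_error = function(e) NA_real_)
      } else NA_real_
      eq2 <- tryCatch(fit_eq2(test, tau, params, config),
                      oxikin_analysis_error = function(e) NULL)
      kinh <- if (!is.null(eq2)) eq2$kinh else NA_real_
      n_st <- if (!is.null(test$meta$conc0) && test$meta$conc0 > 0)
        stoichiometric_n(Ri, tau, test$meta$conc0) else NA_real_
    } else {
      inh_win <- c(t0, t0 + 0.5 * (t_end - t0))
      Rinh <- estimate_rate(test, inh_win)
      prov$windows$Rinh <- inh_win
      Rox2 <- NA_real_
      eq2 <- NULL
      kinh <- NA_real_
      n_st <- NA_real_
    }
  } else {
    # control-like trace analysed as test: the whole record is uninhibited
    win <- post_transient_window(test)
    Rox1 <- estimate_rate(test, win)
    prov$windows$Rox1 <- win
    Rinh <- Rox1
    prov$windows$Rinh <- win
    Rox2 <- NA_real_
    eq2 <- NULL
    kinh <- NA_real_
    n_st <- NA_real_
  }

  classification <- classify_kinetics(
    tau = if (is.null(tau)) NA_real_ else tau, kinh = kinh, Rinh = Rinh,
    Rox1_control = Rox1_ctrl, kp = params$kp, config = config,
    reference = identical(role, "reference"))

  structure(list(
    compound = if (!is.null(test$meta$compound)) test$meta$compound else "unknown",
    classification = classification,
    Rox1 = Rox1, Rinh = Rinh, Rox2 = Rox2,
    tau = tau, Ri = Ri,
    nu_ox1 = if (is.finite(Rox1)) chain_length(Rox1, Ri) else NA_real_,
    nu_inh = if (is.finite(Rinh)) chain_length(Rinh, Ri) else NA_real_,
    nu_ox2 = if (is.finite(Rox2)) chain_length(Rox2, Ri) else NA_real_,
    n_stoich = n_st, kinh = kinh,
    Rox1_control = Rox1_ctrl,
    induction = est, eq2 = eq2, provenance = prov),
    class = "kinetic_report")
}

#' @export
print.kinetic_report <- function(x, ...) {
  cat(sprintf("Kinetic report: %s  [%s]\n", x$compound, x$classification))
  cat(sprintf("  Rox1 = %s nM/s   (nu_ox1 = %s)\n",
              fmt_rate_nM(x$Rox1), format_nu(x$nu_ox1)))
  cat(sprintf("  Rinh = %s nM/s   (nu_inh = %s)\n",
              fmt_rate_nM(x$Rinh), format_nu(x$nu_inh)))
  cat(sprintf("  Rox2 = %s nM/s   (nu_ox2 = %s)\n",
              fmt_rate_nM(x$Rox2), format_nu(x$nu_ox2)))
  cat(sprintf("  tau  = %s min\n",
              if (is.na(x$tau)) "-" else sprintf("%.1f", x$tau / 60)))
  cat(sprintf("  Ri   = %.2f nM/s\n", x$Ri * 1e9))
  cat(sprintf("  n    = %s, kinh = %s M^-1 s^-1\n",
              if (is.na(x$n_stoich)) "-" else sprintf("%.2g", x$n_stoich),
              if (is.na(x$kinh)) "-" else sprintf("%.3g", x$kinh)))
  invisible(x)
}

#' @export
summary.kinetic_report <- function(object, ...) {
  print(object)
  cat("\nProvenance:\n")
  cat(sprintf("  Ri source: %s\n", object$provenance$Ri_source))
  for (w in names(object$provenance$windows))
    cat(sprintf("  window %-13s: %.0f-%.0f s\n", w,
                object$provenance$windows[[w]][1],
                object$provenance$windows[[w]][2]))
  if (!is.null(object$eq2))
    cat(sprintf("  eq2 fit: r2 = %.5f%s\n", object$eq2$r2,
                if (object$eq2$reliable) "" else " [unreliable]"))
  if (!is.na(object$induction$tau))
    cat(sprintf("  tau detector: %s\n", object$induction$method))
  invisible(object)
}

#' @export
coef.kinetic_report <- function(object, ...) {
  c(Rox1 = object$Rox1, Rinh = object$Rinh, Rox2 = object$Rox2,
    tau = object$tau, Ri = object$Ri, nu_ox1 = object$nu_ox1,
    nu_inh = object$nu_inh, nu_ox2 = object$nu_ox2,
    n_stoich = object$n_stoich, kinh = object$kinh)
}

#' Assemble kinetic reports into one parameter table
#'
#' @param reports A list of `kinetic_report` objects (e.g. one per compound).
#' @param display Logical; if `TRUE`, apply the reporting conventions (rates
#'   in nM/s to 3 significant figures, tau in minutes, chain lengths as
#'   integers at/above 10 and one decimal below) and return character
#'   columns. If `FALSE` (default) return numeric SI values.
#' @return A data frame, one row per report.
#' @export
kinetic_table <- function(reports, display = FALSE) {
  stopifnot(all(vapply(reports, inherits, logical(1), "kinetic_report")))
  rows <- lapply(reports, function(r) {
    if (display) {
      data.frame(compound = r$compound, classification = r$classification,
                 Rox1_nMs = fmt_rate_nM(r$Rox1),
                 nu_ox1 = format_nu(r$nu_ox1),
                 tau_min = if (is.na(r$tau)) "-" else sprintf("%.1f", r$tau / 60),
                 Ri_nMs = sprintf("%.1f", r$Ri * 1e9),
                 Rinh_nMs = fmt_rate_nM(r$Rinh),
                 Rox2_nMs = fmt_rate_nM(r$Rox2),
                 nu_inh = format_nu(r$nu_inh),
                 nu_ox2 = format_nu(r$nu_ox2),
                 n = if (is.na(r$n_stoich)) "-" else sprintf("%.1f", r$n_stoich),
                 kinh = if (is.na(r$kinh)) "-" else sprintf("%.2g", r$kinh),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(compound = r$compound, classification = r$classification,
                 Rox1 = r$Rox1, Rinh = r$Rinh, Rox2 = r$Rox2, tau = r$tau,
                 Ri = r$Ri, nu_ox1 = r$nu_ox1, nu_inh = r$nu_inh,
                 nu_ox2 = r$nu_ox2, n_stoich = r$n_stoich, kinh = r$kinh,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.kinetic_report <- function(x, trace = NULL, ...) {
  if (is.null(trace)) stop_analysis("supply the analysed trace to plot")
  plot(trace, ...)
  if (!is.na(x$tau) && !is.na(trace$t_aox))
    graphics::abline(v = trace$t_aox + x$tau, col = 2, lty = 2)
  invisible(x)
}
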