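#' Simulation configuration for an oximetry run
#'
#' Encodes the standard experiment timeline: a pre-initiation baseline, azo
#' initiator injection (t_init = `baseline_s`), and - when an antioxidant is
#' specified - antioxidant injection at the first sample where dissolved O2
#' has dropped to `aox_trigger_frac` of its initial value (instrument practice
#' is to inject at 80-90% of initial O2).
#'
#' @param chain A [chain_params()] object.
#' @param aox An [antioxidant_spec()] or `NULL` for a control run.
#' @param baseline_s Pre-initiation baseline duration, s (>= 0).
#' @param aox_trigger_frac Fraction of initial O2 at which the antioxidant is
#'   injected, in (0, 1); conventional range 0.8-0.9.
#' @param total_s Total simulated time, s (> `baseline_s`).
#' @param dt_sample Sampling interval, s (> 0).
#' @param f_efficiency Optional initiator radical-yield efficiency, metadata
#'   only (the model's primitive is `Ri`).
#' @param include_initiation_uptake Whether initiation itself consumes O2
#'   (each initiating radical adds O2 to become a peroxyl); adds `+Ri` to the
#'   uptake rate. Default `TRUE`. The term is a few percent of the control
#'   rate but dominates the residual uptake under very strong inhibition.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chain = chain_params(), aox = NULL, baseline_s = 60,
                       aox_trigger_frac = 0.85, total_s = 1800,
                       dt_sample = 1, f_efficiency = NULL,
                       include_initiation_uptake = TRUE) {
  stopifnot(inherits(chain, "chain_params"),
            is.null(aox) || inherits(aox, "antioxidant_spec"))
  check_nonneg(baseline_s, "baseline_s")
  check_positive(dt_sample, "dt_sample")
  check_positive(total_s, "total_s")
  if (aox_trigger_frac <= 0 || aox_trigger_frac >= 1)
    stop_domain("aox_trigger_frac must lie strictly between 0 and 1")
  if (total_s <= baseline_s)
    stop_domain("total_s must exceed baseline_s")
  structure(list(chain = chain, aox = aox, baseline_s = baseline_s,
                 aox_trigger_frac = aox_trigger_frac, total_s = total_s,
                 dt_sample = dt_sample, f_efficiency = f_efficiency,
                 include_initiation_uptake = isTRUE(include_initiation_uptake)),
            class = "sim_config")
}

#' Electrode noise model
#'
#' Additive Gaussian noise plus linear drift, emulating a Clark-type oxygen
#' electrode. Replicate counts and noise magnitudes for oximetry runs are
#' rarely reported; the defaults (0.3 uM noise, no drift) are stated choices,
#' not inferred values.
#'
#' @param sigma Noise standard deviation, M (>= 0).
#' @param drift Linear drift, M s^-1 (may be negative).
#' @param seed Integer RNG seed; a fixed seed gives identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 3e-7, drift = 0, seed = 1L) {
  check_nonneg(sigma, "sigma")
  stopifnot(is.numeric(drift), length(drift) == 1L, is.finite(drift))
  structure(list(sigma = sigma, drift = drift, seed = as.integer(seed)),
            class = "noise_model")
}

#' Oxygen-uptake trace
#'
#' A timestamped dissolved-O2 series with the injection events and the system
#' metadata needed to analyse it. Construction validates the trace
#' invariants: strictly increasing times, non-negative O2, and injection
#' ordering.
#'
#' @param times Sample times, s, strictly increasing.
#' @param o2 Dissolved O2 at each time, M, non-negative.
#' @param t_init Initiator injection time, s.
#' @param t_aox Antioxidant injection time, s, or `NA` if none.
#' @param meta Named list of metadata (compound, concentrations, chain
#'   parameters, seed, ...).
#' @return An object of class `ox_trace`.
#' @export
ox_trace <- function(times, o2, t_init, t_aox = NA_real_, meta = list()) {
  if (length(times) != length(o2))
    stop_format("times and o2 must have equal length")
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1]
    stop_format(sprintf("times must be strictly increasing (violated at sample %d)",
                        if (length(bad)) bad + 1L else NA_integer_))
  }
  if (any(!is.finite(o2)) || any(o2 < 0)) {
    bad <- which(!is.finite(o2) | o2 < 0)[1]
    stop_format(sprintf("o2 must be finite and non-negative (violated at sample %d)",
                        bad))
  }
  if (!is.na(t_aox) && t_aox < t_init)
    stop_format("antioxidant injection (t_aox) cannot precede initiation (t_init)")
  structure(list(times = as.numeric(times), o2 = as.numeric(o2),
                 t_init = as.numeric(t_init), t_aox = as.numeric(t_aox),
                 meta = meta),
            class = "ox_trace")
}

#' @export
print.ox_trace <- function(x, ...) {
  cat(sprintf("Oxygen-uptake trace: %d samples, %.0f-%.0f s\n",
              length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  initiator injected at %.0f s", x$t_init))
  if (!is.na(x$t_aox)) cat(sprintf("; antioxidant at %.0f s", x$t_aox))
  cat("\n")
  if (!is.null(x$meta$compound))
    cat(sprintf("  compound: %s\n", x$meta$compound))
  cat(sprintf("  O2: %.1f -> %.1f uM\n",
              x$o2[1] * 1e6, x$o2[length(x$o2)] * 1e6))
  invisible(x)
}

#' @export
plot.ox_trace <- function(x, ..., ylab = "dissolved O2 (uM)",
                          xlab = "time (s)") {
  graphics::plot(x$times, x$o2 * 1e6, type = "l", xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(v = x$t_init, lty = 3)
  if (!is.na(x$t_aox)) graphics::abline(v = x$t_aox, lty = 2)
  invisible(x)
}

# Right-hand side of the chain mechanism ODEs. States: LOO (peroxyl), AoxH,
# LH, O2. Radical balance: initiation - self-termination - trapping, where
# each trapping event removes n_stoich radicals net (non-integer n encodes
# back reactions / stable-adduct formation) while the antioxidant itself is
# consumed at the bimolecular rate.
chain_ode <- function(t, y, p) {
  x <- max(y[1], 0)   # LOO.
  a <- max(y[2], 0)   # AoxH
  LH <- max(y[3], 0)
  trap <- p$kinh * x * a
  dx <- p$Ri - 2 * p$kt * x^2 - p$n_stoich * trap
  da <- -trap
  dLH <- -p$kp * LH * x
  dO2 <- -(p$kp * LH * x + p$Ri_uptake)
  list(c(dx, da, dLH, dO2))
}

run_phase <- function(times, y0, pars) {
  out <- deSolve::lsoda(y = y0, times = times, func = chain_ode, parms = pars,
                        rtol = 1e-8, atol = c(1e-12, 1e-12, 1e-10, 1e-10))
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop(errorCondition(
      sprintf("ODE integration failed (istate = %d) at t ~ %.1f s",
              attr(out, "istate")[1], max(out[, "time"])),
      class = c("oxikin_simulation_error", "oxikin_error")))
  out
}

#' Simulate an oxygen-uptake trace
#'
#' Integrates the peroxyl chain mechanism (initiation, propagation, peroxyl
#' self-termination, antioxidant trapping) with a stiff solver and returns
#' the sampled dissolved-O2 trace under the configured injection timeline:
#' flat baseline, initiator at `baseline_s`, antioxidant at the first sample
#' where O2 has fallen to `aox_trigger_frac` of its initial value. Dissolved
#' O2 is treated as an observable, not a rate-limiting reactant (O2 addition
#' to carbon radicals is orders of magnitude faster than propagation); the
#' trace is truncated if O2 falls below 5% of its initial value, where that
#' assumption fails.
#'
#' @param config A [sim_config()] object.
#' @return An [ox_trace()] (noise-free; see [add_noise()]).
#' @examples
#' tr <- simulate_trace(sim_config(total_s = 600))
#' tr
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ch <- config$chain
  times <- seq(0, config$total_s, by = config$dt_sample)
  t_init <- config$baseline_s

  aox <- config$aox
  has_aox <- !is.null(aox) && aox$conc0 > 0 && aox$kinh > 0
  pars <- list(kp = ch$kp, kt = ch$kt, Ri = ch$Ri,
               kinh = if (has_aox) aox$kinh else 0,
               n_stoich = if (has_aox) aox$n_stoich else 1,
               Ri_uptake = if (config$include_initiation_uptake) ch$Ri else 0)

  pre <- times[times < t_init]
  post_times <- times[times >= t_init]
  grid <- unique(c(t_init, post_times))
  y0 <- c(LOO = 0, AoxH = 0, LH = ch$LH0, O2 = ch$O2_0)

  outA <- run_phase(grid, y0, pars)
  o2A <- outA[, "O2"]
  t_aox <- NA_real_

  if (has_aox) {
    trigger <- config$aox_trigger_frac * ch$O2_0
    hit <- which(o2A <= trigger & outA[, "time"] %in% post_times)
    if (length(hit) > 0) {
      i <- hit[1]
      t_aox <- outA[i, "time"]
      yB <- c(LOO = unname(outA[i, "LOO"]), AoxH = aox$conc0,
              LH = unname(outA[i, "LH"]), O2 = unname(outA[i, "O2"]))
      gridB <- grid[grid >= t_aox]
      outB <- run_phase(gridB, yB, pars)
      keepA <- outA[, "time"] < t_aox
      out <- rbind(outA[keepA, , drop = FALSE], outB)
    } else {
      out <- outA
    }
  } else {
    out <- outA
  }

  sim_t <- out[, "time"]
  sim_o2 <- pmax(out[, "O2"], 0)
  keep <- sim_t %in% post_times
  all_t <- c(pre, sim_t[keep])
  all_o2 <- c(rep(ch$O2_0, length(pre)), sim_o2[keep])

  # truncate once O2 assumption (non-limiting) breaks down
  below <- which(all_o2 < 0.05 * ch$O2_0)
  if (length(below) > 0) {
    cut <- below[1]
    all_t <- all_t[seq_len(cut)]
    all_o2 <- all_o2[seq_len(cut)]
  }

  meta <- list(
    compound = if (has_aox) aox$name else "none",
    conc0 = if (has_aox) aox$conc0 else 0,
    kinh = if (has_aox) aox$kinh else NA_real_,
    n_stoich = if (has_aox) aox$n_stoich else NA_real_,
    initiator = "AAPH",
    kp = ch$kp, kt = ch$kt, Ri = ch$Ri, LH0 = ch$LH0, O2_0 = ch$O2_0,
    include_initiation_uptake = config$include_initiation_uptake,
    f_efficiency = config$f_efficiency
  )
  ox_trace(all_t, all_o2, t_init = t_init, t_aox = t_aox, meta = meta)
}

#' Add electrode noise to a trace
#'
#' Adds seeded Gaussian noise and linear drift to a trace; the noise model is
#' recorded in the metadata. Values are clipped at zero (a Clark electrode
#' cannot report negative O2). With `sigma = 0` and `drift = 0` the trace is
#' returned unchanged.
#'
#' @param trace An [ox_trace()].
#' @param noise A [noise_model()].
#' @return A new [ox_trace()].
#' @export
add_noise <- function(trace, noise) {
  stopifnot(inherits(trace, "ox_trace"), inherits(noise, "noise_model"))
  if (noise$sigma == 0 && noise$drift == 0) return(trace)
  o2 <- with_seed(noise$seed, {
    trace$o2 + stats::rnorm(length(trace$o2), sd = noise$sigma) +
      noise$drift * (trace$times - trace$times[1])
  })
  meta <- trace$meta
  meta$noise <- list(sigma = noise$sigma, drift = noise$drift,
                     seed = noise$seed)
  ox_trace(trace$times, pmax(o2, 0), trace$t_init, trace$t_aox, meta)
}

#' Generate the five-trace demonstration experiment
#'
#' Simulates the standard inhibited-autoxidation experiment set on the
#' liposomal linoleate system: an antioxidant-free control, a chromanol
#' reference ("PMHC-like": kinh = 4.6e4 M^-1 s^-1, n = 2, 1 uM), a weak
#' antioxidant ("TBG-like": kinh = 7e3, n = 0.3, 10 uM), and two retarders
#' ("IBG-like", "DM506-like": kinh = 5e2, n = 1, 10 uM), all under the same
#' chain parameters, with default electrode noise.
#'
#' @param seed Integer seed controlling the electrode noise.
#' @param chain A [chain_params()] object.
#' @param noise_sigma Noise standard deviation, M; 0 for noiseless traces.
#' @param total_s Simulated duration, s.
#' @return Named list of [ox_trace()] objects
#'   (`control`, `PMHC`, `TBG`, `IBG`, `DM506`).
#' @export
generate_experiment_set <- function(seed = 1L, chain = chain_params(),
                                    noise_sigma = 3e-7, total_s = 1800) {
  specs <- list(
    control = NULL,
    PMHC  = antioxidant_spec("PMHC",  conc0 = 1e-6, kinh = 4.6e4, n_stoich = 2),
    TBG   = antioxidant_spec("TBG",   conc0 = 1e-5, kinh = 7e3,   n_stoich = 0.3),
    IBG   = antioxidant_spec("IBG",   conc0 = 1e-5, kinh = 5e2,   n_stoich = 1),
    DM506 = antioxidant_spec("DM506", conc0 = 1e-5, kinh = 5e2,   n_stoich = 1)
  )
  traces <- vector("list", length(specs))
  names(traces) <- names(specs)
  for (i in seq_along(specs)) {
    cfg <- sim_config(chain = chain, aox = specs[[i]], total_s = total_s)
    tr <- simulate_trace(cfg)
    if (noise_sigma > 0)
      tr <- add_noise(tr, noise_model(sigma = noise_sigma,
                                      seed = seed + i - 1L))
    tr$meta$seed <- seed
    traces[[i]] <- tr
  }
  traces
}

#' Generate grouped endpoint replicates matching target summaries
#'
#' Draws `n` replicates per group from a normal law, then rescales them so
#' the realized sample mean and SEM match the targets exactly
#' (moment-matching construction). Used to build endpoint tables (hemolysis,
#' K+ efflux, TBARS) whose group summaries reproduce published-style
#' mean +/- SEM values.
#'
#' @param targets Data frame with columns `group`, `mean`, `sem`, `n`
#'   (`n >= 2`, `sem >= 0`).
#' @param seed Integer RNG seed.
#' @return Data frame with columns `group`, `replicate`, `value` (tidy, one
#'   row per replicate).
#' @examples
#' tab <- generate_endpoint_groups(
#'   data.frame(group = c("control", "AAPH"), mean = c(4.39, 43.31),
#'              sem = c(0.21, 1.29), n = 3), seed = 1)
#' aggregate(value ~ group, tab, mean)
#' @export
generate_endpoint_groups <- function(targets, seed = 1L) {
  stopifnot(is.data.frame(targets),
            all(c("group", "mean", "sem", "n") %in% names(targets)))
  if (any(targets$n < 2)) stop_domain("each group needs n >= 2 replicates")
  if (any(targets$sem < 0)) stop_domain("sem must be non-negative")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(targets)), function(i) {
      n <- targets$n[i]
      m <- targets$mean[i]
      sem <- targets$sem[i]
      z <- stats::rnorm(n)
      v <- if (sem == 0) rep(m, n) else {
        while (stats::sd(z) == 0) z <- stats::rnorm(n)
        m + sem * sqrt(n) * (z - mean(z)) / stats::sd(z)
      }
      data.frame(group = targets$group[i], replicate = seq_len(n), value = v)
    })
    do.call(rbind, rows)
  })
}
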