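#' Chain-oxidation parameter set
#'
#' Bundles the rate constants and concentrations of the peroxyl-radical chain
#' mechanism for an azo-initiated liposomal autoxidation: propagation
#' (`LOO. + LH`), peroxyl self-termination, radical initiation, the oxidizable
#' substrate pool and the dissolved-oxygen reservoir. Only the unsaturated
#' lipid (here methyl linoleate) counts as oxidizable substrate; the saturated
#' phospholipid matrix is inert.
#'
#' When `kt` is not supplied it is calibrated so that the closed-form
#' uninhibited steady-state rate reproduces `Rox_ref` (see [calibrate_kt()]);
#' peroxyl self-termination constants are system specific in
#' microheterogeneous liposome dispersions and are rarely tabulated.
#'
#' @param kp Propagation rate constant, M^-1 s^-1. Default 41, the literature
#'   value for linoleate chains in liposomes.
#' @param kt Peroxyl self-termination rate constant, M^-1 s^-1, or `NULL` to
#'   calibrate from `Rox_ref`.
#' @param Ri Radical initiation rate, M s^-1. Default 4.9e-9 (thermal AAPH
#'   initiation at 37 C, pH 7.4).
#' @param LH0 Initial oxidizable substrate concentration, M. Default 2.74e-3
#'   (methyl linoleate).
#' @param O2_0 Initial dissolved O2, M. Default 217e-6 (air-saturated aqueous
#'   buffer at 37 C).
#' @param kO2 O2-addition rate constant to carbon radicals, M^-1 s^-1.
#'   Informational only: it must be large enough (>= 1e3 * kp) that O2 addition
#'   is never rate limiting, which is the regime the model assumes.
#' @param Rox_ref Observed uninhibited oxidation rate used to calibrate `kt`
#'   when `kt = NULL`, M s^-1. Default 111e-9.
#' @return An object of class `chain_params`.
#' @seealso [uninhibited_rate()], [inhibited_rate()], [calibrate_kt()]
#' @examples
#' ch <- chain_params()
#' uninhibited_rate(ch) * 1e9  # nM/s
#' @export
chain_params <- function(kp = 41, kt = NULL, Ri = 4.9e-9, LH0 = 2.74e-3,
                         O2_0 = 217e-6, kO2 = 3e8, Rox_ref = 111e-9) {
  check_positive(kp, "kp")
  check_positive(Ri, "Ri")
  check_positive(LH0, "LH0")
  check_positive(O2_0, "O2_0")
  check_positive(kO2, "kO2")
  if (kO2 < 1e3 * kp)
    stop_domain("kO2 must be >= 1e3 * kp (fast O2-addition regime)")
  if (is.null(kt)) {
    check_positive(Rox_ref, "Rox_ref")
    kt <- Ri * (kp * LH0 / Rox_ref)^2 / 2
  }
  check_positive(kt, "kt")
  structure(list(kp = kp, kt = kt, Ri = Ri, LH0 = LH0, O2_0 = O2_0, kO2 = kO2),
            class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat("Chain-oxidation parameters\n")
  cat(sprintf("  kp   = %g M^-1 s^-1   (propagation)\n", x$kp))
  cat(sprintf("  kt   = %g M^-1 s^-1   (peroxyl self-termination)\n",
              signif(x$kt, 4)))
  cat(sprintf("  Ri   = %g nM/s        (initiation)\n", x$Ri * 1e9))
  cat(sprintf("  [LH]0 = %g mM, [O2]0 = %g uM\n", x$LH0 * 1e3, x$O2_0 * 1e6))
  invisible(x)
}

#' Antioxidant trapping parameters
#'
#' Describes one peroxyl-radical-trapping compound: its initial concentration,
#' its inhibition rate constant `kinh` (reaction of the antioxidant with LOO.)
#' and its stoichiometric factor `n_stoich`, the number of radicals removed per
#' antioxidant molecule (2 for chromanols such as PMHC; non-integer values
#' arise from back reactions or stable-adduct formation).
#'
#' @param name Compound label.
#' @param conc0 Initial antioxidant concentration, M (>= 0).
#' @param kinh Inhibition rate constant, M^-1 s^-1 (>= 0).
#' @param n_stoich Radicals trapped per molecule, dimensionless (> 0).
#' @return An object of class `antioxidant_spec`.
#' @examples
#' pmhc <- antioxidant_spec("PMHC", conc0 = 1e-6, kinh = 4.6e4, n_stoich = 2)
#' induction_period(pmhc, Ri = 4.9e-9)  # seconds
#' @export
antioxidant_spec <- function(name, conc0, kinh, n_stoich) {
  stopifnot(is.character(name), length(name) == 1L)
  check_nonneg(conc0, "conc0")
  check_nonneg(kinh, "kinh")
  check_positive(n_stoich, "n_stoich")
  structure(list(name = name, conc0 = conc0, kinh = kinh,
                 n_stoich = n_stoich),
            class = "antioxidant_spec")
}

#' @export
print.antioxidant_spec <- function(x, ...) {
  cat(sprintf("Antioxidant '%s': conc0 = %g uM, kinh = %g M^-1 s^-1, n = %g\n",
              x$name, x$conc0 * 1e6, x$kinh, x$n_stoich))
  invisible(x)
}

#' Uninhibited steady-state oxidation rate
#'
#' Classical rate law of the uninhibited chain with propagation rate-limiting
#' and peroxyl self-termination:
#' `R_ox = kp * [LH] * sqrt(Ri / (2 kt))`.
#'
#' @param params A [chain_params()] object.
#' @return Oxidation rate, M s^-1.
#' @export
uninhibited_rate <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  params$kp * params$LH0 * sqrt(params$Ri / (2 * params$kt))
}

#' Inhibited steady-state oxidation rate
#'
#' Instantaneous chain rate when peroxyl radicals are removed predominantly by
#' the antioxidant: `R_inh = kp * [LH] * Ri / (n * kinh * [AoxH])`. Initiation
#' O2 uptake is excluded; this is the chain contribution only, evaluated at
#' the supplied antioxidant concentration.
#'
#' @param params A [chain_params()] object.
#' @param aox An [antioxidant_spec()] with `conc0 > 0` and `kinh > 0`.
#' @return Oxidation rate, M s^-1.
#' @export
inhibited_rate <- function(params, aox) {
  stopifnot(inherits(params, "chain_params"),
            inherits(aox, "antioxidant_spec"))
  if (aox$conc0 <= 0 || aox$kinh <= 0)
    stop_domain(paste("inhibited_rate requires conc0 > 0 and kinh > 0;",
                      "use uninhibited_rate() for the antioxidant-free chain"))
  params$kp * params$LH0 * params$Ri / (aox$n_stoich * aox$kinh * aox$conc0)
}

#' Induction period from the radical balance
#'
#' The induction period ends when the antioxidant pool is exhausted by the
#' radical flux: `tau = n * [AoxH]0 / Ri`.
#'
#' @param aox An [antioxidant_spec()].
#' @param Ri Radical initiation rate, M s^-1 (> 0).
#' @return tau, s.
#' @export
induction_period <- function(aox, Ri) {
  stopifnot(inherits(aox, "antioxidant_spec"))
  check_positive(Ri, "Ri")
  aox$n_stoich * aox$conc0 / Ri
}

#' Stoichiometric factor from a measured induction period
#'
#' Inverts the radical balance: `n = Ri * tau / [AoxH]0`, the number of
#' peroxyl radicals trapped per antioxidant molecule.
#'
#' @param Ri Initiation rate, M s^-1 (> 0).
#' @param tau Induction period, s (>= 0).
#' @param conc0 Antioxidant concentration, M (> 0).
#' @return n, dimensionless.
#' @examples
#' stoichiometric_n(Ri = 4.9e-9, tau = 570, conc0 = 1e-5)  # ~0.28
#' @export
stoichiometric_n <- function(Ri, tau, conc0) {
  check_positive(Ri, "Ri")
  check_nonneg(tau, "tau")
  check_positive(conc0, "conc0")
  Ri * tau / conc0
}

#' Initiation rate from a reference induction period
#'
#' `Ri = n * [AoxH]0 / tau`, using an antioxidant of known stoichiometry as
#' the calibration standard (classically an alpha-tocopherol analogue with
#' n = 2).
#'
#' @param n_ref Stoichiometric factor of the reference antioxidant (> 0).
#' @param conc0 Reference antioxidant concentration, M (> 0).
#' @param tau Measured induction period, s (> 0).
#' @return Ri, M s^-1.
#' @examples
#' initiation_rate(n_ref = 2, conc0 = 1e-6, tau = 414) * 1e9  # nM/s
#' @export
initiation_rate <- function(n_ref, conc0, tau) {
  check_positive(n_ref, "n_ref")
  check_positive(conc0, "conc0")
  check_positive(tau, "tau")
  n_ref * conc0 / tau
}

#' Integrated inhibited-rate-law O2 uptake
#'
#' Cumulative oxygen consumed during the induction period under strong
#' inhibition, from the integrated rate law
#' `U(t) = (kp * [LH] / kinh) * (-ln(1 - t/tau))`. `U` is the positive amount
#' of O2 consumed, i.e. `[O2]_0 - [O2]_t`; it vanishes at `t = 0`, increases
#' strictly, and diverges as `t -> tau` (where the antioxidant runs out and
#' the approximation breaks down).
#'
#' @param t Time since antioxidant addition, s; must satisfy `0 <= t < tau`.
#'   Vectorised.
#' @param tau Induction period, s (> 0).
#' @param params A [chain_params()] object (supplies `kp` and `LH0`).
#' @param kinh Inhibition rate constant, M^-1 s^-1 (> 0).
#' @return Cumulative O2 consumed, M.
#' @export
eq2_uptake <- function(t, tau, params, kinh) {
  stopifnot(inherits(params, "chain_params"))
  check_positive(tau, "tau")
  check_positive(kinh, "kinh")
  if (any(!is.finite(t)) || any(t < 0) || any(t >= tau))
    stop_domain("eq2_uptake is defined for 0 <= t < tau only")
  (params$kp * params$LH0 / kinh) * (-log1p(-t / tau))
}

#' Kinetic chain length
#'
#' `nu = R / Ri`: propagation cycles sustained per initiating radical. Values
#' near or below 1 indicate a fully suppressed chain.
#'
#' @param R Oxidation rate, M s^-1.
#' @param Ri Initiation rate, M s^-1 (> 0).
#' @return nu, dimensionless. Display rounding (integers at/above 10, one
#'   decimal below) is applied by the reporting layer, not here.
#' @export
chain_length <- function(R, Ri) {
  check_positive(Ri, "Ri")
  if (any(!is.finite(R)) || any(R < 0))
    stop_domain("R must be non-negative and finite")
  R / Ri
}

#' Calibrate the termination constant from an observed control rate
#'
#' Inverts the uninhibited steady-state rate law:
#' `kt = Ri * (kp * [LH] / R_ox)^2 / 2`. Feeding the result back into
#' [uninhibited_rate()] reproduces `Rox_observed` exactly.
#'
#' @param Rox_observed Observed uninhibited rate, M s^-1 (> 0).
#' @param kp,LH0,Ri Remaining chain parameters (see [chain_params()]).
#' @return kt, M^-1 s^-1.
#' @export
calibrate_kt <- function(Rox_observed, kp = 41, LH0 = 2.74e-3, Ri = 4.9e-9) {
  check_positive(Rox_observed, "Rox_observed")
  check_positive(kp, "kp")
  check_positive(LH0, "LH0")
  check_positive(Ri, "Ri")
  Ri * (kp * LH0 / Rox_observed)^2 / 2
}

#' Order-of-magnitude kinh estimate for a retarder
#'
#' For compounds that slow the chain without a distinct induction period the
#' integrated rate law is inapplicable; inverting the inhibited rate law at an
#' assumed stoichiometry gives an order-of-magnitude estimate:
#' `kinh ~ kp * [LH] * Ri / (n * R_inh * [AoxH]0)`. Mixed (self + antioxidant)
#' termination is ignored, so the estimate is indicative only; the return
#' value carries an `order_of_magnitude` attribute to make that explicit.
#'
#' @param Rinh Measured retarded rate, M s^-1 (> 0).
#' @param params A [chain_params()] object.
#' @param conc0 Antioxidant concentration, M (> 0).
#' @param n_assumed Assumed stoichiometric factor (> 0), default 1.
#' @return kinh estimate, M^-1 s^-1, with attribute
#'   `order_of_magnitude = TRUE`.
#' @export
estimate_kinh_retarder <- function(Rinh, params, conc0, n_assumed = 1) {
  stopifnot(inherits(params, "chain_params"))
  check_positive(Rinh, "Rinh")
  check_positive(conc0, "conc0")
  check_positive(n_assumed, "n_assumed")
  est <- params$kp * params$LH0 * params$Ri / (n_assumed * Rinh * conc0)
  attr(est, "order_of_magnitude") <- TRUE
  est
}
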