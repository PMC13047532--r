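test_that("slope estimation is exact on linear traces and zero on the baseline", {
  tr <- ox_trace(0:100, 2e-4 - 1e-7 * (0:100), t_init = 0)
  expect_equal(estimate_rate(tr, c(10, 90)), 1e-7, tolerance = 1e-12)
  # window on the flat pre-initiation baseline
  ctrl <- noiseless_set()$control
  expect_identical(estimate_rate(ctrl, c(0, ctrl$t_init - 1)), 0)
  # a rising trace clips at zero rather than reporting a negative rate
  up <- ox_trace(0:100, 1e-4 + 1e-7 * (0:100), t_init = 0)
  expect_identical(estimate_rate(up, c(0, 100)), 0)
  expect_error(estimate_rate(tr, c(0, 2)), class = "oxikin_analysis_error")
})

test_that("induction-period detection separates inhibition from retardation", {
  set0 <- noiseless_set()
  ch <- test_chain()
  # strong antioxidant: clear induction period near the dose/initiation ratio
  # (the standing peroxyl pool trapped at injection shortens it by a few %)
  est <- detect_tau(set0$PMHC)
  expect_false(is.na(est$tau))
  expect_equal(est$tau, 408, tolerance = 0.10)
  expect_identical(est$method, "tangent_intersection")
  # inhibited-phase slope well below the control slope (the window-averaged
  # inhibited uptake includes initiation and the rebuilding radical pool,
  # so "well below" here means under a third of the control rate)
  rinh <- estimate_rate(set0$PMHC, set0$PMHC$t_aox + c(0.1, 0.8) * est$tau)
  expect_lt(rinh, 0.3 * uninhibited_rate(ch))
  # retarders and the control have no inflection
  expect_true(is.na(detect_tau(set0$DM506)$tau))
  expect_true(is.na(detect_tau(set0$IBG)$tau))
  expect_true(is.na(detect_tau(set0$control)$tau))
  # weak antioxidant: faint inflection still detected
  expect_false(is.na(detect_tau(set0$TBG)$tau))
  # curvature-based fallback detector agrees to ~15% on a clear trace
  est2 <- detect_tau(set0$PMHC, analysis_config(tau_method = "second_derivative"))
  expect_equal(est2$tau, est$tau, tolerance = 0.15)
  expect_true(is.na(detect_tau(set0$DM506,
    analysis_config(tau_method = "second_derivative"))$tau))
})

test_that("tau and kinh are recovered accurately in the integrated law's regime", {
  ch <- test_chain()
  for (kinh in c(5e3, 5e4)) {
    tr <- grid_trace(kinh, n = 1)
    tau_nom <- 8000
    est <- detect_tau(tr)
    expect_equal(est$tau, tau_nom, tolerance = 0.05)
    fit <- fit_eq2(tr, est$tau, ch)
    expect_equal(fit$kinh, kinh, tolerance = 0.10)
    expect_true(fit$reliable)
  }
})

test_that("initiation-rate calibration from a reference trace", {
  ch <- test_chain()
  # reference in the validity regime (dose >> peroxyl pool): within 5%
  ref <- grid_trace(4.6e4, n = 2)
  ri <- calibrate_ri(ref, n_ref = 2, conc0 = grid_dose(2))
  expect_equal(as.numeric(ri), ch$Ri, tolerance = 0.05)
  # at the 1 uM study dose the pool trapped at injection biases tau (and
  # hence Ri) upward by under 10%
  ri_demo <- calibrate_ri(noiseless_set()$PMHC, n_ref = 2, conc0 = 1e-6)
  expect_equal(as.numeric(ri_demo), ch$Ri, tolerance = 0.10)
  expect_false(is.null(attr(ri_demo, "tau")))
  # no induction period -> calibration error
  expect_error(calibrate_ri(noiseless_set()$control),
               class = "oxikin_calibration_error")
})

test_that("integrated-law regression is exact on data generated by the law", {
  ch <- test_chain()
  kinh <- 7000; tau <- 570
  t <- seq(0, 1100, by = 1)
  o2 <- rep(2e-4, length(t))
  inh <- t >= 100 & t < 100 + 0.99 * tau
  o2[inh] <- 2e-4 - eq2_uptake(t[inh] - 100, tau, ch, kinh)
  o2[t >= 100 + 0.99 * tau] <- min(o2[inh])
  tr <- ox_trace(t, o2, t_init = 0, t_aox = 100)
  fit <- fit_eq2(tr, tau, ch)
  expect_equal(fit$slope, ch$kp * ch$LH0 / kinh, tolerance = 1e-10)
  expect_equal(fit$kinh, kinh, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$initiation_subtracted)
  # fit methods are mutually consistent
  expect_equal(unname(coef(fit)[["kinh"]]), fit$kinh)
  expect_equal(fitted(fit) + residuals(fit), fit$U, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-15)
  expect_error(fit_eq2(noiseless_set()$control, 400, ch),
               class = "oxikin_analysis_error")
})

test_that("kinh recovery under 1% multiplicative noise is stable across seeds", {
  ch <- test_chain()
  tr <- grid_trace(1e4, n = 1)
  ests <- vapply(1:5, function(s) {
    o2n <- oxikin:::with_seed(s, tr$o2 * (1 + rnorm(length(tr$o2), sd = 0.01)))
    trn <- ox_trace(tr$times, pmax(o2n, 0), tr$t_init, tr$t_aox, tr$meta)
    fit_eq2(trn, detect_tau(trn)$tau, ch)$kinh
  }, numeric(1))
  expect_equal(median(ests), 1e4, tolerance = 0.15)
})

test_that("weak-antioxidant (mixed-termination) kinh is order-correct", {
  # at the 10 uM study dose the weak trap leaves a substantial self-
  # termination share, which biases the integrated-law kinh upward by a few
  # tens of percent; it must stay on the right order and above the
  # antioxidant classification threshold
  ch <- test_chain()
  tr <- noiseless_set()$TBG
  est <- detect_tau(tr)
  fit <- fit_eq2(tr, est$tau, ch)
  expect_equal(fit$kinh, 7000, tolerance = 0.35)
  expect_gt(fit$kinh, 100 * ch$kp)
})

test_that("increasing the trapping constant strictly decreases the inhibited rate", {
  ch <- test_chain()
  rates <- vapply(c(2e3, 7e3, 2e4), function(k) {
    aox <- antioxidant_spec("x", conc0 = 1e-5, kinh = k, n_stoich = 0.5)
    tr <- simulate_trace(sim_config(chain = ch, aox = aox, total_s = 1200))
    estimate_rate(tr, tr$t_aox + c(50, 350))
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("classification follows the rate-constant and rate-ratio rules", {
  cfg <- analysis_config()
  Rox1 <- 111e-9
  expect_identical(classify_kinetics(tau = 500, kinh = 7000, Rinh = 40e-9,
                                     Rox1_control = Rox1), "antioxidant")
  # boundary equality resolves toward the stronger class
  expect_identical(classify_kinetics(tau = 500, kinh = 100 * 41, Rinh = 40e-9,
                                     Rox1_control = Rox1), "antioxidant")
  expect_identical(classify_kinetics(tau = NA, kinh = NA, Rinh = 98e-9,
                                     Rox1_control = Rox1), "retarder")
  expect_identical(classify_kinetics(tau = NA, kinh = NA, Rinh = 0.9 * Rox1,
                                     Rox1_control = Rox1), "retarder")
  expect_identical(classify_kinetics(tau = NA, kinh = NA, Rinh = Rox1,
                                     Rox1_control = Rox1), "inactive")
  expect_identical(classify_kinetics(tau = 500, kinh = 7000, Rinh = 40e-9,
                                     Rox1_control = Rox1, reference = TRUE),
                   "reference")
  expect_error(classify_kinetics(tau = NA, kinh = NA, Rinh = 1e-9,
                                 Rox1_control = NA),
               class = "oxikin_analysis_error")
})

test_that("end-to-end analysis produces a consistent parameter table", {
  set0 <- noiseless_set()
  ch <- test_chain()
  roles <- c(control = "test", PMHC = "reference", TBG = "test",
             IBG = "test", DM506 = "test")
  reports <- lapply(names(set0), function(nm) {
    analyze_trace(set0[[nm]], control = set0$control, reference = set0$PMHC,
                  params = ch, role = roles[[nm]])
  })
  names(reports) <- names(set0)
  expect_identical(vapply(reports, `[[`, "", "classification"),
                   c(control = "inactive", PMHC = "reference",
                     TBG = "antioxidant", IBG = "retarder",
                     DM506 = "retarder"))
  # chain lengths are exact ratios of the reported rates
  for (r in reports) {
    if (is.finite(r$Rox1)) expect_equal(r$nu_ox1, r$Rox1 / r$Ri)
    if (is.finite(r$Rinh)) expect_equal(r$nu_inh, r$Rinh / r$Ri)
    if (is.finite(r$Rox2)) expect_equal(r$nu_ox2, r$Rox2 / r$Ri)
  }
  # control analysed as a test trace: uninhibited throughout
  expect_identical(reports$control$Rinh, reports$control$Rox1)
  expect_identical(reports$control$nu_inh, reports$control$nu_ox1)
  expect_true(is.na(reports$control$tau))
  # weak-antioxidant stoichiometry lands near the published-style value
  expect_gt(reports$TBG$n_stoich, 0.2)
  expect_lt(reports$TBG$n_stoich, 0.4)
  # retarders get a retarded-process rate but no post-inhibition phase
  expect_true(is.na(reports$DM506$Rox2))
  expect_lt(reports$DM506$Rinh, 0.9 * reports$DM506$Rox1_control)
  # table assembly and coef round out the reporting surface
  tab <- kinetic_table(reports)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$compound, c("none", "PMHC", "TBG", "IBG", "DM506"))
  disp <- kinetic_table(reports, display = TRUE)
  expect_type(disp$Rox1_nMs, "character")
  expect_identical(unname(coef(reports$TBG)[["kinh"]]), reports$TBG$kinh)
  expect_output(print(reports$TBG), "antioxidant")
  expect_output(summary(reports$TBG), "Provenance")
})
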