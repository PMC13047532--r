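# oxikin

Kinetic analysis of antioxidant-inhibited lipid peroxidation from
oxygen-uptake traces.

## The problem

A standard way to quantify how well a compound traps lipid peroxyl radicals
is inhibited autoxidation: unsaturated lipid (methyl linoleate) in DMPC
liposomes is oxidized by peroxyl radicals generated at a constant rate
R<sub>i</sub> by a thermal azo initiator (AAPH), and dissolved O₂ is
followed with a Clark electrode. A good antioxidant suppresses oxygen
uptake until it is consumed — an induction period τ — while a weak trap
merely slows the chain (retardation). From one trace and a control, the
classical analysis yields the full kinetic fingerprint of a compound:

- uninhibited rate R<sub>ox</sub> = k<sub>p</sub>[LH]√(R<sub>i</sub>/2k<sub>t</sub>),
- induction period τ = n[AoxH]₀/R<sub>i</sub> (n = radicals trapped per
  molecule; n = 2 for the chromanol reference PMHC),
- inhibition rate constant k<sub>inh</sub> from the integrated rate law
  −Δ[O₂]<sub>t</sub> = (k<sub>p</sub>[LH]/k<sub>inh</sub>)·(−ln(1 − t/τ)),
- kinetic chain lengths ν = R/R<sub>i</sub>,
- a behavioural classification (antioxidant / retarder / inactive).

oxikin implements this pipeline for experimentalists and modellers: a
mechanistic stiff-ODE simulator that emits realistic oximetry traces (no
raw traces are usually deposited with publications, so synthetic data are
first-class here), the parameter-extraction stage, and the
membrane-protection effect statistics (percent protection, Cohen's d from
summary statistics, t-based 95% CIs) used for erythrocyte endpoints such
as hemolysis, K⁺ efflux and TBARS.

## Worked example

Simulate the five-trace experiment (control, 1 µM chromanol reference, a
10 µM weak antioxidant, two 10 µM retarders) and analyse the weak
antioxidant against the control, calibrating R<sub>i</sub> from the
reference trace:

```r
library(oxikin)
ch  <- chain_params()                      # kp = 41, Ri = 4.9 nM/s, kt calibrated
set <- generate_experiment_set(seed = 1)   # five noisy traces
rep_tbg <- analyze_trace(set$TBG, control = set$control,
                         reference = set$PMHC, params = ch)
rep_tbg
#> Kinetic report: TBG  [antioxidant]
#>   Rox1 = 104.0 nM/s   (nu_ox1 = 23)
#>   Rinh = 47.90 nM/s   (nu_inh = 11)
#>   Rox2 = 102.0 nM/s   (nu_ox2 = 23)
#>   tau  = 9.9 min
#>   Ri   = 4.52 nM/s
#>   n    = 0.27, kinh = 9.04e+03 M^-1 s^-1
```

Reading: the pre-injection rate (104 nM/s, chain length 23) matches the
uninhibited control; after injection the compound shows a faint induction
period of ~10 min, traps ~0.3 radicals per molecule, and its
k<sub>inh</sub> ≈ 9×10³ M⁻¹s⁻¹ clears the 100·k<sub>p</sub> threshold, so
it classifies as a (weak) antioxidant rather than a retarder. For weak
traps at these doses mixed termination biases the integrated-law
k<sub>inh</sub> upward by a few tens of percent (see the vignette), so the
value is best read as order-of-magnitude.

Protection statistics from published-style summary data (mean ± SEM,
n = 3):

```r
cohens_d(group_summary(43.31, 1.29, 3), group_summary(4.39, 0.21, 3))
#> [1] 24.31407
percent_reduction(group_summary(4.30, 0.09, 3), group_summary(7.59, 0.13, 3))
#> [1] 43.34651
```

A K⁺-efflux jump from 4.39 to 43.31 (SEM units, n = 3 each) is a
Cohen's d of 24.31 — catastrophic membrane damage — and the treated
hemolysis mean of 4.30 vs the stressor's 7.59 is a 43.3% reduction.

There is also a thin command-line front end:

```sh
Rscript inst/scripts/oxikin.R demo --out demo_out --seed 1
Rscript inst/scripts/oxikin.R calibrate-ri --trace demo_out/PMHC_trace.csv --n 2 --conc 1e-6
```

`demo` regenerates the five-trace experiment, the combined kinetic
parameter table (JSON + text) and the endpoint effect tables,
deterministically for a given seed.

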