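Package: oxikin
Title: Inhibited Lipid-Peroxidation Kinetics from Oxygen-Uptake Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of azo-initiated, antioxidant-inhibited
    lipid peroxidation in liposomes followed by Clark-electrode oximetry.
    Provides closed-form chain-oxidation kinetics (steady-state rates,
    induction periods, stoichiometric factors, the integrated inhibited rate
    law), a stiff-ODE simulator of oxygen-uptake traces with the standard
    initiator/antioxidant injection timeline and electrode noise, extraction
    of kinetic parameters (tau, Ri, k_inh, n, rates and kinetic chain
    lengths) from traces with antioxidant/retarder classification, and
    summary-statistic effect measures (percent protection, Cohen's d,
    t-based confidence intervals) for membrane-protection endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
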