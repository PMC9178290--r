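Package: kneesense
Title: One-at-a-Time Parameter Sensitivity Analysis for Finite-Element
    Knee Joint Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for one-at-a-time parameter
    sensitivity studies of tibiofemoral finite-element simulations.
    Enumerates the perturbation design over ligament, meniscus, contact,
    solver-control and rigid-cylindrical-joint parameters; defines a
    plain-text interchange format for simulation result bundles
    (joint kinematics, per-face tibial contact pressure fields,
    convergence records); extracts four outcome parameters (model
    convergence, valgus kinematics RMSE, peak contact pressure and its
    location on the tibial cartilage); maps aggregated metrics onto a
    0-3 qualitative influence scale; and ships a synthetic generator of
    FE-like result bundles with known injected effects so the whole
    pipeline is testable without a finite-element solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
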