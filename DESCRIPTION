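Package: guardcellsim
Title: System Dynamics Simulation of Guard-Cell Turgor During Stomatal Opening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates turgor pressure and volume dynamics of stomatal guard
    cells when prescribed osmotic water influx, rather than assumed static
    turgor, drives cell expansion. Water influx follows configurable cumulative
    schedules (Maxwell-Boltzmann S-curve, saturating exponential, logistic);
    the guard-cell wall can be soft, rigid, isotropic linear elastic
    (thin-walled cylinder compliance) or viscoelastic (standard linear solid
    with Kelvin delayed strain), and turgor emerges from a quasi-static mass
    balance between the compressible intracellular fluid and wall deformation.
    Includes closed-form and relaxed fixed-point per-step pressure solvers,
    trajectory summaries, modulus calibration by bisection, YAML configuration
    with full parameter echo, CSV/JSON output and a command-line interface
    reproducing eight canonical wall-rheology x influx-shape scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
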