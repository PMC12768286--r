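Package: lysogeny
Title: Evolution of Temperate-Phage Lysis-Lysogeny Decisions in Fluctuating Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and selection-analysis toolkit for the evolutionary
    epidemiology of temperate bacteriophage. Integrates host-phage-arbitrium
    dynamics of a well-mixed bacterial population under constant or
    square-wave influx of susceptible cells, locates the periodic attractor
    of the resident system, and computes class frequencies, reproductive
    values and instantaneous selection gradients on the lysogenisation
    probability and prophage reactivation rate in normal and stressed
    (SOS-induced) host cells. Nested root-finding on period-averaged
    selection gradients yields (co)evolutionarily stable strategies for
    fixed traits and for arbitrium-dependent reaction norms, including
    boundary optima. Utilities cover configuration files, CSV/JSON export
    of trajectories and selection profiles, invasion (Floquet) exponents as
    an independent fitness check, and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
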