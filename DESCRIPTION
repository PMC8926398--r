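Package: smfretkin
Title: Kinetic Analysis of Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and kinetic analysis of single-molecule FRET
    (smFRET) time traces of membrane-protein conformational dynamics,
    built around the workflow used to resolve voltage- and pH-dependent
    motions of the hHv1 voltage-sensor S4 segment in liposomes.
    Provides a continuous-time Markov simulator of multi-state FRET
    trajectories with donor/acceptor photophysics (crosstalk,
    photobleaching, blinking), crosstalk-corrected FRET computation and
    Autotrace-style trace selection, Gaussian-mixture state discovery
    with SSE-reduction model selection, hidden-Markov idealization with
    direct rate-constant optimization and fixed emission centers,
    ensemble statistics (state occupancies, transition-density plots,
    equilibrium constants), and Nernst-voltage / ACMA flux-assay
    utilities for liposome electrophysiology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
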