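Package: neocoupler
Title: Analysis of Discontinuous Oscillations and Hippocampal-Prefrontal
    Coupling in Neonatal Multi-Site Recordings
Version: 0.1.0
Authors@R:
    person("neocoupler", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection and quantification of discontinuous network
    oscillations (theta bursts), sharp waves and ripples in neonatal
    extracellular recordings, together with spectral power (Welch and
    Morlet), undirected coupling (imaginary coherence), directed coupling
    (generalized partial directed coherence from vector autoregressive
    fits), spike-LFP phase locking with Rayleigh testing, sharp-wave
    triggered firing, and optogenetic pulse-train response metrics.
    Includes a seeded synthetic-session generator that emulates the
    statistical structure of dual-region (hippocampus CA1 and prelimbic
    cortex) recordings so that every analysis stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
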