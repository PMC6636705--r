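Package: laminaprobe
Title: Layer-Resolved Analysis of Corticospinal Volleys, PSTHs and
    TMS-Conditioned H-Reflexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resolving sub-millisecond
    components of the first corticospinal volley. Provides seeded generators
    for layer-5 spike trains and subthreshold EPSPs evoked by superficial
    versus deep cortical stimulation, depth-graded epidural volley sweeps,
    motoneuron-pool recruitment during TMS-conditioned H-reflex trials, and
    an adaptive random-dot-motion task with a simulated observer. Analysis
    stages cover population peri-stimulus time histogram compilation with
    zero-phase 400-2000 Hz band-pass filtering and first-peak latency
    extraction, a Monte Carlo shuffle test for latency differences, D/I1
    volley latency measurement, the two-step (rough then fine) search for the
    earliest facilitation delay of the H-reflex, and task-epoch facilitation
    statistics with Bonferroni-adjusted pre-planned comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
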