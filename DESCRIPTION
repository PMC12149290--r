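Package: nbackPFC
Title: Analysis of Prefrontal Delay Activity in the Oculomotor N-Back Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and analysing the oculomotor n-back working-memory
    paradigm: trial and event scheduling for 1-back/2-back rules, behavioral outcome
    taxonomy (rule vs. memory errors), saccade detection and trajectory-angle
    statistics, Poisson generalized-linear decomposition of delay-period spike
    counts into visual, extinction, memory, order and rule components with
    directional-index neuron classification, pseudo-population decoding of the
    task rule with a resampled train/validate protocol, and stimulation-effect
    statistics. Includes a synthetic-session generator (trials, inhomogeneous-
    Poisson spike trains, 1-kHz eye traces, choice behavior with a memory-erasure
    stimulation manipulation) with a ground-truth sidecar for recovery testing,
    plus a plain-text session directory format with readers and writers and a
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
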