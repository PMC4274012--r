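Package: memsim
Title: Stochastic Simulation of Gene-Expression Memory Across Cell Divisions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic simulation of a two-state (random-telegraph)
    promoter model of gene expression coupled to scheduled cell-division
    events, together with the fluctuation statistics used to quantify
    expression memory in cell lineages: normalized variance (squared
    coefficient of variation), autocorrelation functions of the
    volume-normalized protein concentration and their half-decay time,
    subclone relaxation time courses, in-silico whole-cell photobleaching
    recovery, and a synthetic-data generator emulating time-lapse tracking
    tables and flow-cytometry snapshots.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
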