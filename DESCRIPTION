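Package: pullscope
Title: Simulated Force Spectroscopy of Coarse-Grained Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulated single-molecule force spectroscopy of
    structure-based (Go-type) protein models and for comparing unfolding
    mechanisms across models of different resolution. Provides a minimal
    C-alpha Go-model steered molecular dynamics engine (Langevin dynamics,
    constant-velocity tether pulling, temperature scans, perturb-and-relax
    protocols), smoothed native-contact order parameters and contact-map
    observables, cross-model normalization of temperature, time and force
    scales (two-state melting fits, relaxation-time extraction, Jarzynski
    work analysis, Flyvbjerg-Petersen block averaging), and a TM-score
    based structural taxonomy of unfolding pathways with clustering and
    pathway-flow graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
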