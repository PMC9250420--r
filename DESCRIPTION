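Package: shiftstate
Title: Bayesian Comparison of Simulated Chemical-Shift Ensembles with
    Solid-State NMR for Conformational State Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decides which simulated conformational-state ensemble of a
    membrane protein best explains experimental solid-state NMR chemical
    shifts. Per-nucleus ensembles of predicted chemical shifts (SPARTA+,
    SHIFTX2 or generic long-format tables) are modelled with a Bayesian
    skew-normal likelihood sampled by an adaptive MCMC sampler; nuclei able
    to discriminate candidate open states are selected by credible-interval
    and effect-size criteria; experiment-vs-simulation difference shifts
    (delta-delta chemical shifts against a closed reference state) assign
    each discriminating nucleus to a state; a flowchart classifier sorts
    every assigned nucleus into marker classes. Includes a ground-truth
    synthetic-data generator, gate-distance and trajectory-window utilities,
    and an end-to-end pipeline with tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    coda,
    jsonlite,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
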