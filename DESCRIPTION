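Package: okterm
Title: Okazaki Fragment Terminus Analysis and Lagging-Strand Maturation
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of Okazaki fragment sequencing (OK-seq) libraries from
    DNA ligase I depletion experiments, together with a stochastic simulator
    of lagging-strand synthesis and barrier-limited nick translation.
    Computes per-origin efficiency metrics from strand-specific fragment
    counts, strand-aware meta-profiles of fragment 5'/3' termini around
    nucleosome dyads and transcription-factor binding sites, and density
    profiles of retained DNA polymerase alpha initiator tracts.  The
    simulator models stochastic origin firing, fork progression, priming at
    nucleosome-repeat spacing, iterative strand-displacement/cleavage cycles
    impeded by chromatin barriers, ligation, and continued nick translation
    at unsealed nicks during ligase depletion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
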