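Package: mirepress
Title: Quantitative Analysis of MicroRNA Expression and Target Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating endogenous microRNA abundance to the
    repression of perfectly complementary reporter targets. Implements
    small-RNA read assignment to mature microRNA references with a
    5'-anchored mismatch policy, reads-per-million normalisation and
    guide/passenger (star) arm classification; dual-luciferase repression
    with per-day empty-vector normalisation and paired t-tests; canonical
    7-nt seed-site prediction in 3'UTR sets, target-site abundance, and
    cloning-junction screens for adventitious sites; a nearest-neighbour
    free-energy score for perfectly paired microRNA:target duplexes; and a
    log-linear expression-to-repression model fitted by ordinary least
    squares with confidence intervals and occupancy (Ago-1 RIP) analysis.
    A synthetic-data generator with known ground truth supports end-to-end
    testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
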