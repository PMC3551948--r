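Package: adnorm
Title: Adaptive Normalization for Immunoprecipitation Enrichment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalization and target calling for immunoprecipitation (IP)
    versus mock-control enrichment experiments such as RIP-chip or CLIP-style
    assays. Models each IP measurement as mock background plus a non-negative
    binding signal and an unknown additive per-replicate offset, estimates the
    offsets adaptively from the least IP-enriched ("background") genes found
    by ranking Mock-minus-IP differences, selects the background-set size by
    locating the onset of piecewise linearity in the ranked difference curve,
    and calls enriched targets with a moderated t statistic and
    permutation-estimated false discovery rate. Includes simulators of
    idealized IP experiments and mock-versus-mock null designs, and a
    read-count binning adapter for sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
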