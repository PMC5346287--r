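Package: bicodonbias
Title: Differential Codon-Pair Usage Between Lowly and Highly Abundant Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical analysis of bicodon (adjacent codon pair) usage in
    coding sequences of lowly versus highly abundant proteins. Implements
    length-matched rejection sampling of the two sequence sets, counting over
    the 3,904-bicodon universe, the pause propensity score (difference in
    relative synonymous bicodon usage), per-bicodon Fisher exact tests with an
    optional Stirling factorial mode, chi-squared residual scores against
    single-codon expectations, a codon-shuffling empirical null, a four-way
    bicodon classification, clustered heat-map exports, cross-organism
    shared-bicodon tables, ribosome-occupancy-filtered candidate lists and
    synonymous-SNP pause-propensity reports. Includes a synthetic proteome
    generator with planted codon-pair couplings for end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
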