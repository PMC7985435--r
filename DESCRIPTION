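Package: tetradci
Title: Quantifying Chromatid Interference from Tetrad Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers from tetrad genotype tables, classifies
    double crossovers into two-, three- and four-strand types, and quantifies
    chromatid interference (CI) with a signed per-DCO score whose mean ranges
    from -1 (complete negative CI) to +1 (complete positive CI). Provides
    goodness-of-fit and signed-rank tests of CI for genome-wide, per-chromosome
    and centromere-partitioned DCO groups, a weighted regression of CI on
    physical inter-crossover distance, and a meiosis simulator with a tunable
    chromatid-choice bias that supplies truth-labelled synthetic tetrads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    vctrs,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
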