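Package: itraqdiff
Title: Differential Protein Expression from 4-plex iTRAQ Reporter Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for 4-plex iTRAQ (isobaric tag) differential
    protein-expression analysis: global median normalization of peptide-level
    reporter-ion ratios, peptide-to-protein rollup (mean, sample SD, peptide
    count), a one-tailed one-sample t-test of ratios against unity, a
    three-stage filter cascade (minimum peptide count, fold-change band,
    significance), and a transparent right-tailed Fisher's-exact functional
    enrichment over GMT term sets with keyword filtering. Ships a synthetic
    peptide-level data generator with known ground truth so every stage is
    testable end to end, plus the published per-timepoint differential tables
    of a 6-OHDA striatal lesion study as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
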