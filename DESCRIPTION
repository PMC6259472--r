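Package: cktrace
Title: Deuterium-Labeling Calculations for Cytokinin Biosynthetic Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for stable-isotope (deuterium) labeling studies of
    isoprenoid cytokinins by tandem mass spectrometry. Provides exact and
    nominal mass arithmetic over chemical formulas with explicit deuterium,
    ppm mass-error checks, natural isotopologue pattern computation by
    per-element convolution, a registry of the common isoprenoid cytokinins
    with the hydroxyl-propionylation derivatization rule, generation of
    multiple-reaction-monitoring (MRM) isotopomer transition ladders, and
    conversion of measured isotopomer peak areas into natural-abundance
    corrected tracer:tracee (t/t) ratios by non-negative least squares
    deconvolution, with replicate statistics, a synthetic-data simulator,
    CSV batch processing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    pracma,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
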