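Package: robseg
Title: Meiotic Segregation of Robertsonian Trivalents and the
    Interchromosomal Effect in Preimplantation Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the molecular karyotypes of blastocysts from
    Robertsonian translocation carriers into trivalent meiotic segregation
    products (alternate, adjacent, 3:0/other), categorises non-translocation
    chromosome abnormalities (normal, aneuploid, mosaic) for
    interchromosomal-effect analysis against a non-translocation control arm,
    and runs the stratified 2x2 contingency statistics (chi-square, Fisher's
    exact test, odds ratios with Woolf confidence intervals). Includes a
    compact karyotype-string parser/writer, a Monte-Carlo cohort simulator
    with ground-truth labels for every embryo, tidy tabulation and plotting
    of segregation tables and chromosome abnormality spectra, and a
    tab-separated cohort file format with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
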