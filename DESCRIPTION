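Package: ldbridges
Title: Quantitative Models of Lipid Droplet Protein Targeting and Surface Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and biophysical analyses for lipid droplet (LD) cell
    biology: an exact binomial random-placement null model for object-based
    colocalization of protein foci with LDs, a diffusion-limited kinetic model
    of ER-to-LD protein targeting through membrane bridges with estimation of
    the number of ER-LD connections, apparent diffusion coefficients from
    tubule FRAP recovery, interfacial tension from drop-weight (drop-volume)
    tensiometry with the Harkins-Brown correction, and kernel-density summaries
    of LD size populations. Includes seeded synthetic-data generators for every
    input type so all stages are testable end to end, plus image segmentation
    of two-channel fluorescence fields into particle tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
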