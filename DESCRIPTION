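Package: solnmr
Title: Solution-State NMR Characterization of Multidomain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the solution-NMR analysis chain
    used to characterize multidomain proteins with flexible linkers:
    neighbor-corrected random-coil chemical-shift prediction, combined amide
    secondary chemical shifts and structured/flexible segmentation,
    heteronuclear 15N{1H}-NOE profiles, minimal-shift chemical-shift
    perturbation mapping of binding sites against unassigned bound-state
    spectra, distance-restraint bookkeeping (disulfide and hydrogen-bond
    expansion), NMR-ensemble superposition and RMSD statistics, and
    steady-state one-site binding-isotherm fitting for biosensor data.
    Includes a synthetic-data generator that emulates a two-domain protein
    joined by a flexible linker, with planted ground truth for every
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
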