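Package: cascadesign
Title: Fragment-Based Design of Complementary Peptides and Antibody Scaffold Grafting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the rational design of antibody-like binders against
    linear epitopes of amyloidogenic proteins. Mines beta-strand-paired
    peptide fragments from protein structures using a DSSP-style backbone
    hydrogen-bond criterion, assembles complementary peptides (paratopes)
    for epitope windows by linking overlapping fragments (the cascade
    procedure), scores candidates by structural support and intrinsic
    solubility, tiles a target sequence such as islet amyloid polypeptide
    (IAPP) with epitope windows, and grafts the designed paratopes into
    engineered single-domain antibody and monobody scaffold templates,
    emitting sequence-ready construct panels. Includes an ideal beta-sheet
    generator so the whole pipeline runs on synthetic structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
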