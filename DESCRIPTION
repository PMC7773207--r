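Package: zahnreihe
Title: Tooth Replacement Wave Models for Polyphyodont Ontogenetic Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing tooth replacement dynamics across an
    ontogenetic growth series of polyphyodont amniotes, built around the
    Early Triassic cynodont Galesaurus planiceps. Provides a curated
    specimen table with uncertainty and missingness conventions, min-max
    normalization of basal skull length, ontogenetic stage classification,
    ordinary least squares trends of postcanine counts against skull size,
    a discrete-stage Zahnreihe (replacement wave) simulator over an ordered
    tooth-locus lattice with distal locus addition, mesial locus
    retirement, canine replacement cessation and alternating incisor
    waves, inference of wave spacing, wave direction and left-right
    synchrony from per-locus observations, and a synthetic-data generator
    for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
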