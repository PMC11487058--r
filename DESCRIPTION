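Package: xolint
Title: Interference Length and Companion Measures of Meiotic Crossover
    Interference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies meiotic crossover interference from per-chromosome
    crossover positions.  The central statistic is the interference length,
    the interference-induced increase in the mean distance over all
    crossover pairs relative to a Poisson null in which crossovers are
    placed independently along the chromosome; chromosomes with zero or one
    crossover enter through missing-pair bookkeeping weighted at the
    chromosome length.  The package also provides the classical
    coefficient-of-coincidence curve with its interference distance, gamma
    shape fits to adjacent inter-crossover distances, bootstrap and
    permutation inference, coordinate-space conversion between genetic (Mb)
    and cytological (um) positions, simulators for canonical
    crossover-placement scenarios, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
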