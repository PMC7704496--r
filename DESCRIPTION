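Package: nmrbind
Title: Protein-Oligonucleotide Binding Analysis from NMR and Fluorescence
    Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of protein-oligonucleotide binding
    equilibria as monitored by NMR and tryptophan-fluorescence titrations.
    Implements the ligand-depletion (quadratic) binding isotherm for N
    independent, identical sites per oligonucleotide, its tight-binding
    limit, fast- and slow-exchange observation models for chemical shifts
    and peak intensities, dissociation-constant estimation from
    fluorescence quench curves, binding-stoichiometry estimation from
    normalized chemical-shift trajectories, combined chemical-shift
    perturbation mapping with sigma0 thresholds and cross-ligand consensus
    epitopes, seeded synthetic-data generators for all of the above, and
    plain-text readers/writers with a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
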