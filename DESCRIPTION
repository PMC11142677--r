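Package: redqueen
Title: Mechanistic Simulation of PRDM9-Driven Recombination Hotspot Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of the intra-genomic
    Red Queen dynamics of PRDM9-dependent recombination hotspots. Meiosis is
    modeled mechanistically: chemical-equilibrium binding of PRDM9 to its
    target sites, double-strand break induction at bound sites, a
    symmetric-binding requirement for homologue pairing, crossover formation,
    and biased gene conversion through repair off the homologue. The package
    also provides the closed-form summary statistics of the model (symmetric
    binding rate, fertility, haplo-insufficiency, allele diversity), a
    mean-field analytical layer (erosion rate, intrinsic allele age, regime
    prediction under gene dosage), preset parameterisations, and parameter
    grid experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
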