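Package: epidermisevo
Title: Homeostatic Epidermis Simulation with Base-Pair Mutation Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional hybrid cellular automaton of homeostatic
    human epidermis in which keratinocyte division and death are governed by
    a diffusible growth-factor niche anchored at the basal layer. Every cell
    carries an in silico genome restricted to a gene panel, accumulating
    base-pair substitutions at gene-specific Poisson rates with a
    cytosine-enriched mutational signature, so that mutations act as
    heritable cell-fate markers. Driver selection is modelled without
    altering division rates: NOTCH1-class mutants resist displacement by
    neighbouring divisions (blocking probability f0) and TP53-class mutants
    are spared from ultraviolet kill events on scheduled sun days
    (kill fraction theta_s). The package converts simulated clones into
    sequencing-realistic variant allele frequencies via gamma-distributed
    read depths and binomial variant reads, and provides clone-size
    statistics (first incomplete moment, neutral-drift theory,
    Kolmogorov-Smirnov comparisons, departure-from-homeostasis metric)
    together with a logistic-growth surrogate for scanning ultraviolet
    exposure schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    MASS,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
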