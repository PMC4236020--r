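Package: cortigen
Title: Deterministic Models of Cortical Neurogenesis and Comparative Analysis of Gyrencephaly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling mammalian cortical neurogenesis and for the
    comparative statistics of cortical folding. Implements a deterministic
    multi-lineage model that predicts adult cortical neuron numbers from
    neuroepithelial founder-pool size, neurogenic period, cell-cycle length
    and the proportional occurrence of seven progenitor lineages; exhaustive
    grid inference of best-fit neurogenic programs; trade-off inversions of
    the forward model (required neurogenic period or founder pool for a
    target neuron count); stage-structured (Lefkovitch) matrix and ODE
    analyses of proliferative versus asymmetrically dividing progenitors;
    founder-pool estimation from ventricular geometry; segmented allometric
    scaling with AIC model selection, minimum-energy hierarchical clustering,
    Jenks natural breaks and group contrasts of brain weight per gestation
    day; and a simplified phylogenetic trait layer (Brownian and delta
    models, ancestral state reconstruction, transition-direction counting)
    with seeded synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
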