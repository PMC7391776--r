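Package: evomicro
Title: Eco-Evolutionary Simulation of Digital Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based eco-evolutionary simulator of digital microbes on a
    2D lattice. Cells carry evolvable metabolic genomes (enzymes and
    transporters with Michaelis-Menten kinetics), grow by converting two
    essential building blocks into a biomass budget, divide into empty
    neighbouring sites, die stochastically with toxicity-elevated hazard, and
    exchange metabolites with a shared environment fed by a single resource.
    Includes the reference 9-metabolite / 59-reaction chemical universe,
    procedural universe generation, genome mutation operators (stretch
    duplication/deletion/inversion/translocation, point mutations, gene
    discovery, horizontal transfer), renewing lineage markers, metabolic
    genotype clade tracking with Muller-table export, network topology
    classification by energy substrate, lineage-removal dependency assays,
    and gene-frequency / proteome PCA matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
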