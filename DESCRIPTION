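Package: CloneArch
Title: Single-Cell Clonal Architecture and Phylogeny Inference for AML
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs tumour sub-clonal architecture from single-cell
    multiplex Q-PCR genotyping of tracked driver mutations, as used in
    NPM1c-mutant acute myeloid leukaemia. Converts per-well allelic
    discrimination signals into QC-filtered ternary genotype calls against a
    diploid control locus, collapses cells into sub-clones with
    dropout-aware merging and a binomial detection-limit model, infers
    rooted clonal phylogenies by maximum parsimony with complete
    enumeration of all equally parsimonious trees, and derives mutation
    order, truncal status, reiterated (parallel) mutations and
    xenograft/relapse clone-set mappings. A seeded synthetic-data module
    generates chip-level inputs (sorted compartments, 48/96-well chips,
    allele dropout, xenograft bottlenecks) so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'panel.R'
    'simulate.R'
    'genotyping.R'
    'clones.R'
    'phylogeny.R'
    'newick.R'
    'interpretation.R'
    'io.R'
    'pipeline.R'
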