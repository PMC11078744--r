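Package: patrikin
Title: Pedigree Simulation, IBD-Based Kinship Inference and Social
    Structure Analysis for Ancient Cemetery Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates multi-generation patrilineal communities with
    configurable steppe-style kinship rules (female exogamy, polygyny,
    levirate unions, consanguinity avoidance), transmits founder-labelled
    genomes through the pedigree by Poisson-crossover meiosis to obtain
    true identity-by-descent (IBD) and runs-of-homozygosity (ROH)
    segments, degrades them with an ancient-DNA-style observation model,
    re-infers pairwise relatedness degrees and second-degree subtypes
    from segment summaries, assembles pedigrees under sex, age and
    uniparental-haplogroup constraints, computes social-practice
    statistics (patriliny, exogamy, shared-partner unions), builds
    weighted IBD-sharing networks with within/between-site degree
    partitions and permutation tests, and performs Bayesian radiocarbon
    calibration with pedigree-derived generational priors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
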