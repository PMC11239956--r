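Package: skyisland
Title: Population Structure, Barcode Delimitation and Paleoclimate Niche
    Hindcasting for Montane Sky-Island Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-based population structure analysis (allele-level
    hierarchical AMOVA with Phi statistics and permutation tests, Slatkin
    pairwise F_ST, exact Hardy-Weinberg tests, per-locus diversity), DAPC-style
    genetic clustering (PCA, k-means with BIC model selection, discriminant
    membership probabilities), COI barcode species delimitation (Kimura
    2-parameter distances with pairwise deletion, barcode-gap partitioning,
    statistical-parsimony haplotype networks), and a paleoclimate ensemble
    niche-modeling engine that hindcasts presence-only species distributions
    across glacial-interglacial cycles using a benthic delta-18-O forcing
    curve as an interpolation covariate. Includes seeded synthetic-data
    generators (nested Balding-Nichols genotypes, barcode alignments with
    shared haplotypes, affine forcing-driven climate histories) so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    e1071,
    glmnet,
    MASS,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
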