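Package: equibiome
Title: Equine Faecal Microbiota Analysis and IBD Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 16S OTU tables from equine faecal samples
    in an inflammatory bowel disease (IBD) case-control setting: rare-OTU
    filtering, rarefaction, alpha diversity (Chao1, Shannon, Pielou) with
    rank-scaled four-factor ANOVA, Jaccard beta diversity with distance-based
    redundancy analysis and permutation tests, Firmicutes/Bacteroidota ratio
    statistics, a split-control bootstrap test of fold-change concordance
    between two IBD cohorts against a permutation null, taxon-enrichment
    chi-squared tests, and a class-weighted single-hidden-layer neural-network
    disease classifier with repeated cross-validation. Includes a calibrated
    Dirichlet-multinomial synthetic cohort generator with ground truth, so
    every stage is testable without access to the embargoed study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    jsonlite
Config/testthat/edition: 3
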