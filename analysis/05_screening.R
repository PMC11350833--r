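#!/usr/bin/env Rscript

# Diagnostic screening model: merge the two IBD groups into the positive
# class, select up to 200 OTUs by rank-sum tests on the 80% training split,
# grid-search hidden size {3,6,9} x decay {0.1..0.4} with 5x5 repeated
# stratified CV and class-balancing weights, refit the best network, and
# evaluate the untouched 20% test split.

suppressMessages(library(equibiome))

dir.create("results/screening", recursive = TRUE, showWarnings = FALSE)
seed <- 20240904

rarefied <- read_otu_table("results/cohort/rarefied.tsv")
meta <- read_metadata("results/cohort/metadata.tsv")

res <- screen_ibd(rarefied, meta, ann_config(seed = seed))
print(res)

utils::write.table(res$cv$grid, "results/screening/cv_grid.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(res$evaluation$probabilities,
                   "results/screening/test_predictions.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
imp <- data.frame(otu_id = names(res$importance),
                  importance = unname(res$importance))
imp <- imp[order(-imp$importance), ]
utils::write.table(imp, "results/screening/importance.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(sprintf("top-5 input OTUs carry %.1f%% of the Garson importance",
                100 * sum(imp$importance[1:5])))

cm <- res$evaluation$confusion
message(sprintf("test confusion: TP %d, FN %d, FP %d, TN %d",
                cm["ibd", "ibd"], cm["control", "ibd"],
                cm["ibd", "control"], cm["control", "control"]))
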