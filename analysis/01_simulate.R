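#!/usr/bin/env Rscript

# Build the synthetic study cohort: a three-group equine faecal 16S data set
# (27 control, 30 survey IBD, 19 acute IBD horses) with known ground truth,
# then apply the preprocessing every later stage shares: drop OTUs without
# at least 10 reads in two samples, and rarefy to the smallest library.

suppressMessages(library(equibiome))

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
seed <- 20240901

cfg <- default_config()
coh <- generate_cohort(cfg, seed = seed)
message(sprintf("cohort: %d samples x %d OTUs, depths %d-%d",
                nrow(coh$counts), ncol(coh$counts),
                min(rowSums(coh$counts)), max(rowSums(coh$counts))))

write_otu_table(coh$counts, "results/cohort/otu_table.tsv", otus_as_rows = TRUE)
write_taxonomy(coh$taxonomy, "results/cohort/taxonomy.tsv")
write_metadata(coh$metadata, "results/cohort/metadata.tsv")

filtered <- filter_rare_otus(coh$counts, min_reads = 10, min_samples = 2)
message(sprintf("rare-OTU filter: %d of %d OTUs retained",
                ncol(filtered), ncol(coh$counts)))
rarefied <- rarefy(filtered, depth = NULL, seed = seed + 1)
message(sprintf("rarefied every sample to %d reads", sum(rarefied[1, ])))
write_otu_table(rarefied, "results/cohort/rarefied.tsv", otus_as_rows = TRUE)

truth <- data.frame(otu_id = coh$truth$da_ids,
                    log2fc_survey = coh$truth$delta[, "survey_ibd"],
                    log2fc_acute = coh$truth$delta[, "acute_ibd"])
utils::write.table(truth, "results/cohort/truth_da.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message(sprintf("ground truth: %d DA OTUs, realised effect correlation %.3f",
                nrow(truth), cor(truth$log2fc_survey, truth$log2fc_acute)))
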