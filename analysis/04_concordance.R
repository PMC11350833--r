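#!/usr/bin/env Rscript

# Fold-change concordance between the two IBD cohorts: screen candidate OTUs
# by unadjusted Welch t-tests, correlate the control-vs-survey and
# control-vs-acute mean-difference vectors over a split control group
# (bootstrapped 100x), compare against a permutation null of random
# labelling (100x), and run the two taxon-enrichment chi-squared tests.

suppressMessages(library(equibiome))

dir.create("results/concordance", recursive = TRUE, showWarnings = FALSE)
seed <- 20240903

rarefied <- read_otu_table("results/cohort/rarefied.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
meta <- read_metadata("results/cohort/metadata.tsv")
truth <- utils::read.table("results/cohort/truth_da.tsv", sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)

conc <- concordance_test(rarefied, meta, alpha = 0.05, n_boot = 100,
                         n_perm = 100, seed = seed)
print(conc)
message(sprintf("one-sided empirical p vs the permutation null: %.4f",
                conc$empirical_p))
message(sprintf("true DA OTUs recovered by the screen: %.0f%%",
                100 * mean(truth$otu_id %in% conc$candidates)))

utils::write.table(
  data.frame(otu_id = conc$candidates, delta_survey = conc$delta_survey,
             delta_acute = conc$delta_acute),
  "results/concordance/candidate_deltas.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)
utils::write.table(
  data.frame(replicate = seq_along(conc$r_boot), r_boot = conc$r_boot,
             r_null = conc$r_null),
  "results/concordance/correlations.tsv", sep = "\t",
  row.names = FALSE, quote = FALSE)
summary_df <- data.frame(
  r_point = conc$r, r_boot_mean = mean(conc$r_boot),
  r_null_mean = mean(conc$r_null), welch_t = conc$test$statistic,
  welch_df = conc$test$df, welch_p = conc$test$p,
  empirical_p = conc$empirical_p)
utils::write.table(summary_df, "results/concordance/summary.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

# enrichment tests use the ground-truth DA set as the externally derived
# differential-abundance list
da_set <- intersect(truth$otu_id, colnames(rarefied))
sign_res <- sign_agreement_test(rarefied, meta, da_set)
message(sprintf(paste0("sign-consistent changes in %.1f%% of DA OTUs; ",
                       "chi-squared = %.2f, p = %.3g"),
                100 * sign_res$consistent_fraction, sign_res$statistic,
                sign_res$p))

fb_res <- fb_count_enrichment(da_set, colnames(rarefied), tax)
message(sprintf(paste0("F:B OTU-count ratio: %.2f over all OTUs, ",
                       "%.2f among DA OTUs; chi-squared = %.2f, p = %.3g"),
                fb_res$universe_ratio, fb_res$da_ratio, fb_res$statistic,
                fb_res$p))
enrich <- data.frame(
  test = c("sign_agreement", "fb_count"),
  statistic = c(sign_res$statistic, fb_res$statistic),
  df = c(sign_res$df, fb_res$df),
  p = c(sign_res$p, fb_res$p))
utils::write.table(enrich, "results/concordance/enrichment.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
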