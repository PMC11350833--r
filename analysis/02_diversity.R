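#!/usr/bin/env Rscript

# Alpha diversity (Chao1, Shannon, Pielou) with the rank-scaled four-factor
# ANOVA, then beta diversity: Jaccard dissimilarities and distance-based
# redundancy analysis constrained on health status, age, gender and body
# condition, with permutation tests by term and by axis.

suppressMessages(library(equibiome))

dir.create("results/diversity", recursive = TRUE, showWarnings = FALSE)
seed <- 20240902

rarefied <- read_otu_table("results/cohort/rarefied.tsv")
meta <- impute_metadata(read_metadata("results/cohort/metadata.tsv"))
stopifnot(identical(rownames(rarefied), meta$sample_id))

alpha <- alpha_diversity(rarefied)
utils::write.table(alpha, "results/diversity/alpha.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
for (metric in c("chao1", "shannon", "pielou")) {
  an <- rank_anova(alpha[[metric]], meta)
  utils::write.table(an, sprintf("results/diversity/anova_%s.tsv", metric),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  message(sprintf("%s: status F_%d,%d = %.3f, p = %.3f", metric,
                  an$df[1], an$df[nrow(an)], an$statistic[1], an$p[1]))
}

d <- jaccard_matrix(rarefied)
utils::write.table(as.matrix(d), "results/diversity/jaccard.tsv", sep = "\t",
                   quote = FALSE)

fit <- dbrda_fit(d, meta)
message(sprintf("db-RDA: constraints explain %.1f%% of inertia",
                100 * fit$prop_explained))
utils::write.table(data.frame(sample_id = meta$sample_id, fit$site_scores),
                   "results/diversity/cap_scores.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

# 9,999 permutations per term (with the other terms retained) and per axis
pt_margin <- dbrda_permtest(d, meta, n_perm = 9999, scope = "margin",
                            seed = seed)
pt_axis <- dbrda_permtest(d, meta, n_perm = 9999, scope = "axis",
                          seed = seed + 1)
utils::write.table(pt_margin, "results/diversity/dbrda_terms.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(pt_axis, "results/diversity/dbrda_axes.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
for (i in seq_len(nrow(pt_margin)))
  message(sprintf("term %-9s F = %.3f, p = %.4f", pt_margin$term[i],
                  pt_margin$statistic[i], pt_margin$p[i]))
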