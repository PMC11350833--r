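#!/usr/bin/env Rscript

# Core composition of the healthy hindgut community (phylum- and
# family-level mean relative abundances) and the log10 Firmicutes/
# Bacteroidota ratio, modelled against host covariates with Pearson
# follow-ups for significant numeric terms.

suppressMessages(library(equibiome))

dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)

rarefied <- read_otu_table("results/cohort/rarefied.tsv")
tax <- read_taxonomy("results/cohort/taxonomy.tsv")
meta <- impute_metadata(read_metadata("results/cohort/metadata.tsv"))

for (rk in c("phylum", "family")) {
  ts <- taxon_summary(rarefied, tax, rk, meta)
  utils::write.table(ts, sprintf("results/composition/%s_summary.tsv", rk),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
ts <- taxon_summary(rarefied, tax, "phylum", meta)
top <- head(ts, 3)
message("control-group phylum means: ",
        paste(sprintf("%s %.1f%%", top$taxon, 100 * top$control),
              collapse = ", "))

fb <- fb_ratio(rarefied, tax)
utils::write.table(fb, "results/composition/fb_ratio.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
# both conventions of the cohort-level ratio, labelled
message(sprintf("F/B mean of per-sample ratios: %.2f; ratio of summed reads: %.2f",
                mean(10^fb$log10_fb), sum(fb$f_reads) / sum(fb$b_reads)))

mod <- fb_model(fb, meta)
utils::write.table(mod$anova, "results/composition/fb_anova.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(mod$pearson, "results/composition/fb_pearson.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
if (nrow(mod$pearson) > 0) {
  for (i in seq_len(nrow(mod$pearson)))
    message(sprintf("%s vs log10 F/B: r = %.2f, t_%d = %.2f, p = %.4f",
                    mod$pearson$term[i], mod$pearson$r[i], mod$pearson$df[i],
                    mod$pearson$statistic[i], mod$pearson$p[i]))
} else {
  message("no numeric covariate significantly explained the F/B ratio")
}
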