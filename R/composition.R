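#' Taxon-level relative-abundance summary
#'
#' Aggregates per-sample relative abundances to phylum or family level and
#' reports the unweighted mean across the samples of each study group and
#' overall, so each animal carries equal weight (mean of per-sample
#' proportions, not pooled reads). Taxa are sorted by overall mean,
#' descending; OTUs without a usable rank assignment are retained under
#' `"unassigned"`.
#'
#' @param counts Samples x OTUs count matrix (typically rarefied).
#' @param tax A `taxonomy_table`.
#' @param rank `"phylum"` or `"family"`.
#' @param meta Metadata aligned with `counts` rows (for the group means).
#' @return Data frame with columns `taxon`, one column per status group,
#'   and `overall`; each group column sums to 1 over taxa.
#' @export
taxon_summary <- function(counts, tax, rank = c("phylum", "family"), meta) {
  rank <- match.arg(rank)
  stopifnot(nrow(meta) == nrow(counts))
  props <- relative_abundance(counts)
  taxon <- tax_rank(tax, colnames(counts), rank = rank)
  # taxa x samples per-sample aggregated proportions
  agg <- rowsum(t(props), group = taxon)
  groups <- levels(meta$status)
  out <- data.frame(taxon = rownames(agg), stringsAsFactors = FALSE)
  for (g in groups) {
    sel <- meta$status == g
    out[[g]] <- if (any(sel)) rowMeans(agg[, sel, drop = FALSE]) else NA_real_
  }
  out$overall <- rowMeans(agg)
  out <- out[order(-out$overall), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample log10 Firmicutes/Bacteroidota ratio
#'
#' Sums reads of OTUs assigned to phylum Firmicutes (F) and Bacteroidota (B)
#' per sample and returns `log10(F/B)`. When either sum is zero a
#' pseudocount of 0.5 is added to both, keeping the ratio finite without
#' perturbing typical samples.
#'
#' @param counts Samples x OTUs count matrix.
#' @param tax A `taxonomy_table` covering the table.
#' @return Data frame with columns `sample_id`, `f_reads`, `b_reads`,
#'   `log10_fb`.
#' @export
fb_ratio <- function(counts, tax) {
  phyla <- tax_rank(tax, colnames(counts), rank = "phylum")
  is_f <- phyla == "Firmicutes"
  is_b <- phyla == "Bacteroidota"
  if (!any(is_f) && !any(is_b))
    stop("table contains no Firmicutes and no Bacteroidota OTUs")
  f <- rowSums(counts[, is_f, drop = FALSE])
  b <- rowSums(counts[, is_b, drop = FALSE])
  zero <- f == 0 | b == 0
  fr <- ifelse(zero, f + 0.5, f)
  br <- ifelse(zero, b + 0.5, b)
  data.frame(sample_id = rownames(counts), f_reads = f, b_reads = b,
             log10_fb = log10(fr / br), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Model the F/B ratio against host covariates
#'
#' Four-factor ANOVA (status, age, gender, body condition score) on the
#' per-sample log10 F/B ratio, followed by a Pearson correlation for each
#' numeric term whose ANOVA p-value falls below `alpha`.
#'
#' @param fb Output of [fb_ratio()].
#' @param meta Imputed metadata aligned with `fb`.
#' @param terms Model terms in sequential order.
#' @param alpha Significance level gating the follow-up correlations.
#' @return List with `anova` (sequential ANOVA table) and `pearson` (data
#'   frame of `term`, `r`, `statistic` (t), `df`, `p`; empty when no numeric
#'   term is significant).
#' @export
fb_model <- function(fb, meta, terms = c("status", "age", "gender", "bcs"),
                     alpha = 0.05) {
  stopifnot(nrow(fb) == nrow(meta))
  y <- fb$log10_fb
  if (stats::var(y) == 0) {
    warning("constant F/B ratio: F undefined, reporting F = 0, p = 1")
    tab <- data.frame(term = c(terms, "Residuals"),
                      df = c(rep(1L, length(terms)),
                             length(y) - length(terms) - 1L),
                      sumsq = 0, meansq = 0,
                      statistic = c(rep(0, length(terms)), NA),
                      p = c(rep(1, length(terms)), NA),
                      stringsAsFactors = FALSE)
    return(list(anova = tab,
                pearson = data.frame(term = character(0), r = numeric(0),
                                     statistic = numeric(0), df = numeric(0),
                                     p = numeric(0))))
  }
  dat <- cbind(data.frame(.y = y), meta[terms])
  fml <- stats::reformulate(terms, response = ".y")
  a <- stats::anova(stats::lm(fml, data = dat))
  tab <- data.frame(term = trimws(rownames(a)), df = a$Df, sumsq = a$`Sum Sq`,
                    meansq = a$`Mean Sq`, statistic = a$`F value`,
                    p = a$`Pr(>F)`, row.names = NULL, stringsAsFactors = FALSE)
  numeric_terms <- terms[vapply(meta[terms], is.numeric, logical(1))]
  sig <- tab$term[!is.na(tab$p) & tab$p < alpha]
  cors <- lapply(intersect(sig, numeric_terms), function(tm) {
    ct <- stats::cor.test(meta[[tm]], y)
    data.frame(term = tm, r = unname(ct$estimate),
               statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  pearson <- if (length(cors) > 0) do.call(rbind, cors) else
    data.frame(term = character(0), r = numeric(0), statistic = numeric(0),
               df = numeric(0), p = numeric(0))
  list(anova = tab, pearson = pearson)
}
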