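#' Per-sample alpha diversity
#'
#' Observed richness, bias-corrected Chao1, Shannon entropy (natural log) and
#' Pielou evenness for each sample. Chao1 uses the bias-corrected form
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))} with \eqn{F_1, F_2} the singleton
#' and doubleton counts, which stays finite when no doubletons are observed.
#' Pielou evenness is `NA` for samples with a single taxon (its maximum
#' entropy is 0).
#'
#' Counts are normally rarefied to a common depth first (see [rarefy()]) so
#' richness is comparable across samples; this is recommended, not enforced.
#'
#' @param counts Samples x OTUs count matrix.
#' @return Data frame with columns `sample_id`, `s_obs`, `chao1`, `shannon`,
#'   `pielou`.
#' @export
alpha_diversity <- function(counts) {
  empty <- rowSums(counts) == 0
  if (any(empty))
    stop("empty sample(s): ", paste(rownames(counts)[empty], collapse = ", "))
  s_obs <- rowSums(counts > 0)
  f1 <- rowSums(counts == 1)
  f2 <- rowSums(counts == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  p <- relative_abundance(counts)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  shannon <- -rowSums(plogp)
  pielou <- ifelse(s_obs > 1, shannon / log(s_obs), NA_real_)
  data.frame(sample_id = rownames(counts), s_obs = as.integer(s_obs),
             chao1 = chao1, shannon = shannon, pielou = pielou,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-scaled multi-factor ANOVA
#'
#' Replaces the response by mid-ranks (ties averaged) and fits an ordinary
#' least-squares ANOVA with sequential (Type-I) sums of squares in the given
#' term order -- by default health status, then age, gender and body
#' condition score. Rank scaling makes the test robust to the skewed scale of
#' diversity estimates.
#'
#' @param values Numeric per-sample response, aligned with `meta` rows.
#' @param meta Imputed metadata (see [impute_metadata()]).
#' @param terms Model terms, in order; columns of `meta`.
#' @return Data frame with per-term `df`, `sumsq`, `meansq`, `statistic`
#'   (F) and `p`, ending with a `Residuals` row.
#' @export
rank_anova <- function(values, meta, terms = c("status", "age", "gender", "bcs")) {
  stopifnot(length(values) == nrow(meta))
  miss <- setdiff(terms, names(meta))
  if (length(miss) > 0)
    stop("terms not in metadata: ", paste(miss, collapse = ", "))
  r <- rank(values)
  if (stats::var(r) == 0) {
    warning("constant response: F undefined, reporting F = 0, p = 1")
    out <- data.frame(term = c(terms, "Residuals"),
                      df = c(rep(1L, length(terms)),
                             length(r) - length(terms) - 1L),
                      sumsq = 0, meansq = 0,
                      statistic = c(rep(0, length(terms)), NA),
                      p = c(rep(1, length(terms)), NA),
                      stringsAsFactors = FALSE)
    return(out)
  }
  dat <- cbind(data.frame(.rank = r), meta[terms])
  fml <- stats::reformulate(terms, response = ".rank")
  tab <- stats::anova(stats::lm(fml, data = dat))
  data.frame(term = trimws(rownames(tab)), df = tab$Df, sumsq = tab$`Sum Sq`,
             meansq = tab$`Mean Sq`, statistic = tab$`F value`,
             p = tab$`Pr(>F)`, row.names = NULL, stringsAsFactors = FALSE)
}
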