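#' Vectorised Welch two-sample t-test over matrix columns
#'
#' Computes the Welch t statistic, Welch-Satterthwaite degrees of freedom and
#' two-sided p-value for every column of `x`, comparing rows `a` against rows
#' `b`. Columns with zero variance in both groups get p = 1 (no evidence).
#'
#' @param x Samples x features numeric matrix.
#' @param a,b Disjoint row index vectors (or names) of the two groups.
#' @return Data frame with `statistic`, `df`, `p`, one row per column of `x`.
#' @keywords internal
welch_t_columns <- function(x, a, b) {
  xa <- x[a, , drop = FALSE]
  xb <- x[b, , drop = FALSE]
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)  # guard fp negatives
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # no within-group variance: identical means carry no evidence (p = 1);
  # different constant levels are complete separation (p = 0)
  degen <- se2 == 0
  sep <- degen & ma != mb
  tt[degen] <- 0
  tt[sep] <- sign(ma - mb)[sep] * Inf
  df[degen] <- NA_real_
  p[degen] <- 1
  p[sep] <- 0
  data.frame(statistic = tt, df = df, p = p, row.names = colnames(x),
             stringsAsFactors = FALSE)
}

#' Screen candidate differentially abundant OTUs
#'
#' Per-OTU Welch two-sample t-tests on (rarefied) counts, control vs survey
#' IBD and control vs acute IBD. An OTU is a candidate when either comparison
#' yields unadjusted p < `alpha`; no multiplicity correction is applied --
#' this is a deliberately liberal screen whose false positives are handled
#' downstream by the concordance test.
#'
#' @param counts Samples x OTUs count matrix.
#' @param meta Metadata aligned with `counts` rows (`status` used).
#' @param alpha Unadjusted significance threshold (default 0.05).
#' @return Character vector of candidate OTU ids (column-order of `counts`).
#' @export
screen_candidates <- function(counts, meta, alpha = 0.05) {
  stopifnot(nrow(meta) == nrow(counts))
  ctrl <- which(meta$status == "control")
  surv <- which(meta$status == "survey_ibd")
  acute <- which(meta$status == "acute_ibd")
  p_s <- welch_t_columns(counts, ctrl, surv)$p
  p_a <- welch_t_columns(counts, ctrl, acute)$p
  colnames(counts)[p_s < alpha | p_a < alpha]
}

#' Mean-abundance difference vector
#'
#' \eqn{\Delta_j = \bar{x}_{a,j} - \bar{x}_{b,j}} over the candidate OTUs, in
#' the given id order.
#'
#' @param counts Samples x OTUs count matrix.
#' @param ids_a,ids_b Disjoint, nonempty sample id/index sets.
#' @param otus Candidate OTU ids.
#' @return Named numeric vector of differences.
#' @export
mean_difference <- function(counts, ids_a, ids_b, otus) {
  if (length(otus) == 0) stop("empty candidate OTU set")
  if (length(ids_a) == 0 || length(ids_b) == 0) stop("empty sample group")
  if (length(intersect(ids_a, ids_b)) > 0) stop("sample groups overlap")
  colMeans(counts[ids_a, otus, drop = FALSE]) -
    colMeans(counts[ids_b, otus, drop = FALSE])
}

#' Fold-change consistency statistic
#'
#' Pearson correlation between the survey-IBD and acute-IBD mean-difference
#' vectors over the shared candidate OTU set.
#'
#' @param d1,d2 Aligned mean-difference vectors, length >= 3.
#' @return Pearson correlation coefficient.
#' @export
consistency_stat <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("difference vectors differ in length")
  if (length(d1) < 3) stop("need at least 3 candidate OTUs")
  if (stats::var(d1) == 0) stop("zero variance in the first difference vector")
  if (stats::var(d2) == 0) stop("zero variance in the second difference vector")
  stats::cor(d1, d2)
}

split_controls <- function(ctrl) {
  half <- sample(ctrl, floor(length(ctrl) / 2))
  list(c1 = half, c2 = setdiff(ctrl, half))
}

#' Split-control bootstrap of the consistency correlation
#'
#' The two IBD-vs-control comparisons share the control group, which by
#' itself induces a positive correlation between the two difference vectors.
#' Each bootstrap replicate therefore partitions the controls at random into
#' two halves: the survey-IBD differences use one half, the acute-IBD
#' differences the other, so the two estimates share no control animals. The
#' candidate OTU set is screened once on the full groups and held fixed
#' across replicates (only the control split varies; re-screening inside each
#' replicate is available via `rescreen`).
#'
#' @param counts Samples x OTUs count matrix.
#' @param meta Metadata aligned with `counts`.
#' @param alpha Screening threshold passed to [screen_candidates()].
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param candidates Optional pre-computed candidate set (e.g. an externally
#'   derived differential-abundance list); default screens internally.
#' @return Numeric vector of `n_boot` correlations.
#' @export
bootstrap_consistency <- function(counts, meta, alpha = 0.05, n_boot = 100,
                                  seed = 1, candidates = NULL) {
  stopifnot(nrow(meta) == nrow(counts))
  ctrl <- which(meta$status == "control")
  surv <- which(meta$status == "survey_ibd")
  acute <- which(meta$status == "acute_ibd")
  if (length(ctrl) < 4) stop("need at least 4 control samples to split")
  if (is.null(candidates)) candidates <- screen_candidates(counts, meta, alpha)
  if (length(candidates) < 3)
    stop("fewer than 3 candidate OTUs; cannot correlate")
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) {
    halves <- split_controls(ctrl)
    d_s <- mean_difference(counts, halves$c1, surv, candidates)
    d_a <- mean_difference(counts, halves$c2, acute, candidates)
    consistency_stat(d_s, d_a)
  }, numeric(1))
}

#' Permutation null for the consistency correlation
#'
#' Empirical null distribution of the bootstrap statistic under random
#' labelling: each replicate permutes the status labels across all samples
#' (preserving group sizes), re-screens candidates under the permuted
#' labels -- so selection effects propagate into the null -- splits the
#' permuted controls, and computes the consistency correlation. Replicates
#' yielding fewer than 3 candidates are redrawn (at most 50 consecutive
#' retries).
#'
#' A fixed candidate set may instead be supplied via `candidates`, in which
#' case the screen is skipped inside replicates (faster, but the null then
#' ignores selection effects).
#'
#' With `n_splits > 1` each permutation replicate averages the correlation
#' over that many control splits. A single-split replicate carries extra
#' split noise that the split-averaged bootstrap mean does not, so comparing
#' `mean(r_boot)` against single-split null draws is conservative;
#' `n_splits` of about 10 makes the null draws distributionally comparable
#' to the bootstrap mean and gives a calibrated empirical test (see
#' [concordance_test()]).
#'
#' @inheritParams bootstrap_consistency
#' @param n_perm Number of permutation replicates (default 100).
#' @param n_splits Control splits averaged within each replicate (default 1,
#'   the plain procedure).
#' @return Numeric vector of `n_perm` null correlations.
#' @export
permutation_null <- function(counts, meta, alpha = 0.05, n_perm = 100, seed = 1,
                             candidates = NULL, n_splits = 1) {
  stopifnot(nrow(meta) == nrow(counts))
  if (sum(meta$status == "control") < 4)
    stop("need at least 4 control samples to split")
  set.seed(seed)
  out <- numeric(n_perm)
  i <- 1
  failures <- 0
  while (i <= n_perm) {
    pm <- meta
    pm$status <- sample(meta$status)
    cand <- if (is.null(candidates)) screen_candidates(counts, pm, alpha) else candidates
    if (length(cand) < 3) {
      failures <- failures + 1
      if (failures >= 50)
        stop("50 consecutive permutations yielded fewer than 3 candidates")
      next
    }
    failures <- 0
    ctrl <- which(pm$status == "control")
    surv <- which(pm$status == "survey_ibd")
    acute <- which(pm$status == "acute_ibd")
    rs <- vapply(seq_len(n_splits), function(j) {
      halves <- split_controls(ctrl)
      consistency_stat(mean_difference(counts, halves$c1, surv, cand),
                       mean_difference(counts, halves$c2, acute, cand))
    }, numeric(1))
    out[i] <- mean(rs)
    i <- i + 1
  }
  out
}

#' Compare bootstrap and null correlation distributions
#'
#' Welch two-sample t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided) of the bootstrapped correlations against the permutation null.
#'
#' @param r_b Bootstrap correlations.
#' @param r_p Null correlations.
#' @return List with `statistic` (t), `df` and `p`.
#' @export
compare_dists <- function(r_b, r_p) {
  if (length(r_b) < 2 || length(r_p) < 2)
    stop("both distributions need at least 2 values")
  ht <- stats::t.test(r_b, r_p)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Full concordance analysis
#'
#' Convenience wrapper running the candidate screen, the point estimate of
#' the consistency correlation (full control group on both sides), the
#' split-control bootstrap, the permutation null and the Welch comparison,
#' all reproducibly from one seed.
#'
#' Besides the Welch comparison, the result carries a one-sided empirical
#' p-value `(1 + #\{r_null >= mean(r_boot)\}) / (1 + n_perm)`. The Welch
#' test treats the replicate correlations as independent draws, but the
#' bootstrap replicates share the observed labelling (whose selection effect
#' is a single draw from the relabelling distribution), which makes that
#' test anticonservative under label exchangeability; the empirical
#' comparison with `n_splits` of about 10 is calibrated (see the package
#' vignette).
#'
#' @inheritParams permutation_null
#' @param n_boot Number of bootstrap replicates.
#' @param n_perm Number of permutation replicates.
#' @return List of class `concordance_result` with elements `candidates`,
#'   `delta_survey`, `delta_acute`, `r`, `r_boot`, `r_null`, `test`
#'   (the [compare_dists()] summary) and `empirical_p`.
#' @export
concordance_test <- function(counts, meta, alpha = 0.05, n_boot = 100,
                             n_perm = 100, seed = 1, candidates = NULL,
                             n_splits = 1) {
  if (is.null(candidates)) candidates <- screen_candidates(counts, meta, alpha)
  ctrl <- which(meta$status == "control")
  d_s <- mean_difference(counts, ctrl, which(meta$status == "survey_ibd"), candidates)
  d_a <- mean_difference(counts, ctrl, which(meta$status == "acute_ibd"), candidates)
  r_boot <- bootstrap_consistency(counts, meta, alpha, n_boot, seed = seed,
                                  candidates = candidates)
  r_null <- permutation_null(counts, meta, alpha, n_perm, seed = seed + 1L,
                             n_splits = n_splits)
  structure(list(candidates = candidates, delta_survey = d_s, delta_acute = d_a,
                 r = consistency_stat(d_s, d_a), r_boot = r_boot,
                 r_null = r_null, test = compare_dists(r_boot, r_null),
                 empirical_p = (1 + sum(r_null >= mean(r_boot))) /
                   (1 + length(r_null))),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance over %d candidate OTUs: r = %.3f\n",
              length(x$candidates), x$r))
  cat(sprintf("bootstrap mean r = %.3f (n = %d), null mean r = %.3f (n = %d)\n",
              mean(x$r_boot), length(x$r_boot), mean(x$r_null),
              length(x$r_null)))
  cat(sprintf("Welch t_%.2f = %.2f, p = %.3g\n", x$test$df, x$test$statistic,
              x$test$p))
  invisible(x)
}

#' Are abundance changes sign-consistent across the two IBD groups?
#'
#' An OTU counts as consistent when its control-vs-survey and
#' control-vs-acute mean differences (full control group on both sides) have
#' equal, strictly nonzero signs; a zero difference counts as inconsistent.
#' Tests whether consistency is more frequent among a differential-abundance
#' (DA) OTU set than among the remaining OTUs, with a Yates-corrected 2x2
#' chi-squared test.
#'
#' @param counts Samples x OTUs count matrix.
#' @param meta Metadata aligned with `counts`.
#' @param da_set Character vector of DA OTU ids (subset of the universe).
#' @param universe OTU ids over which consistency is evaluated; defaults to
#'   all columns of `counts`.
#' @return List of class `enrichment_result`: `observed` 2x2 table,
#'   `expected`, `statistic`, `df`, `p`, and `consistent_fraction` among the
#'   DA set.
#' @export
sign_agreement_test <- function(counts, meta, da_set, universe = colnames(counts)) {
  if (!all(da_set %in% universe)) stop("da_set must be a subset of the universe")
  ctrl <- which(meta$status == "control")
  d_s <- mean_difference(counts, ctrl, which(meta$status == "survey_ibd"), universe)
  d_a <- mean_difference(counts, ctrl, which(meta$status == "acute_ibd"), universe)
  consistent <- sign(d_s) == sign(d_a) & sign(d_s) != 0
  is_da <- universe %in% da_set
  obs <- rbind(da = c(consistent = sum(consistent & is_da),
                      inconsistent = sum(!consistent & is_da)),
               non_da = c(sum(consistent & !is_da), sum(!consistent & !is_da)))
  ht <- suppressWarnings(stats::chisq.test(obs, correct = TRUE))
  if (any(ht$expected < 1))
    warning("expected cell below 1; chi-squared approximation is poor ",
            "(consider an exact test)")
  structure(list(observed = obs, expected = ht$expected,
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 consistent_fraction = sum(consistent & is_da) / sum(is_da)),
            class = "enrichment_result")
}

#' F/B OTU-count enrichment among DA OTUs
#'
#' Tests whether the Firmicutes:Bacteroidota OTU-count ratio among a
#' differential-abundance set deviates from the ratio over the whole OTU
#' universe, with a two-cell goodness-of-fit chi-squared (df = 1): expected
#' counts are proportional to the universe F:B split, scaled to the number
#' of F+B OTUs in the DA set.
#'
#' @param da_set DA OTU ids.
#' @param universe All OTU ids under consideration.
#' @param tax A `taxonomy_table`.
#' @return List of class `enrichment_result`: `observed` (F, B counts in the
#'   DA set), `expected`, `statistic`, `df`, `p`, `da_ratio`,
#'   `universe_ratio`.
#' @export
fb_count_enrichment <- function(da_set, universe, tax) {
  phyla_u <- tax_rank(tax, universe, rank = "phylum")
  nf_u <- sum(phyla_u == "Firmicutes")
  nb_u <- sum(phyla_u == "Bacteroidota")
  if (nf_u == 0 || nb_u == 0)
    stop("universe must contain Firmicutes and Bacteroidota OTUs")
  phyla_d <- tax_rank(tax, da_set, rank = "phylum")
  nf_d <- sum(phyla_d == "Firmicutes")
  nb_d <- sum(phyla_d == "Bacteroidota")
  if (nf_d + nb_d == 0)
    stop("DA set contains no Firmicutes or Bacteroidota OTUs")
  obs <- c(Firmicutes = nf_d, Bacteroidota = nb_d)
  ht <- suppressWarnings(
    stats::chisq.test(obs, p = c(nf_u, nb_u) / (nf_u + nb_u)))
  structure(list(observed = obs, expected = ht$expected,
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, da_ratio = nf_d / nb_d,
                 universe_ratio = nf_u / nb_u),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("chi-squared enrichment test\n")
  print(x$observed)
  cat(sprintf("X-squared = %.3f, df = %d, p = %.3g\n", x$statistic,
              as.integer(x$df), x$p))
  invisible(x)
}
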