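#' Jaccard-family dissimilarity matrix
#'
#' Quantitative mode (default) computes the abundance-weighted Jaccard
#' dissimilarity \eqn{2B/(1+B)} with \eqn{B} the Bray-Curtis dissimilarity
#' (the `vegdist` convention); binary mode computes the classical
#' presence/absence Jaccard distance \eqn{1 - |A \cap B| / |A \cup B|}.
#'
#' @param counts Samples x OTUs count matrix.
#' @param binary Use presence/absence instead of abundances.
#' @return A `dist` object over samples; entries in `[0, 1]`.
#' @export
jaccard_matrix <- function(counts, binary = FALSE) {
  if (nrow(counts) < 2) stop("need at least two samples")
  zero <- rowSums(counts) == 0
  d <- suppressWarnings(vegan::vegdist(counts, method = "jaccard", binary = binary))
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(rownames(counts)[zero], collapse = ", "),
            "; affected dissimilarities set to 0")
    m <- as.matrix(d)
    m[zero, ] <- 1  # empty vs non-empty share nothing
    m[, zero] <- 1
    m[zero, zero] <- 0  # two empty samples defined as identical
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  d
}

dbrda_formula <- function(terms) {
  if (length(terms) == 0) stats::as.formula("d ~ 1")
  else stats::reformulate(terms, response = "d")
}

#' Distance-based redundancy analysis
#'
#' Constrained analysis of principal coordinates: the distance matrix is
#' double-centred and eigendecomposed, the principal coordinates are
#' projected onto the column space of the model matrix built from `terms`
#' (treatment coding for factors), and the fitted part is eigendecomposed
#' into constrained (CAP) axes. Implemented via [vegan::dbrda()], the method
#' of the ecology stack this analysis belongs to. With an empty term list the
#' result is a plain principal-coordinates analysis.
#'
#' Negative eigenvalues arising from non-Euclidean distances (the Jaccard
#' family is not Euclidean) are excluded from the reported inertias.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param meta Imputed metadata aligned with the rows of `d`.
#' @param terms Character vector of constraint terms (columns of `meta`);
#'   may be empty.
#' @return A list of class `dbrda_result` with elements `model` (the vegan
#'   object), `eig_constrained`, `eig_unconstrained`, `total_inertia`,
#'   `constrained_inertia`, `residual_inertia`, `prop_explained` and
#'   `site_scores` (sample scores on the constrained axes, if any).
#' @export
dbrda_fit <- function(d, meta, terms = c("status", "age", "gender", "bcs")) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (!is.null(meta) && nrow(meta) != n)
    stop("metadata rows do not match the distance matrix")
  fml <- dbrda_formula(terms)
  environment(fml) <- environment()  # the formula must see `d` and `meta`
  mod <- vegan::dbrda(fml, data = meta, na.action = stats::na.fail)
  # vegan rescales large distances by sqrt(n-1) but leaves bounded
  # dissimilarities as-is; report everything on the variance scale
  # (eigenvalues of the double-centred matrix over n - 1, as in rda)
  adj <- if (is.null(mod$adjust)) 1 else mod$adjust
  k <- adj^2 / (n - 1)
  eig_c <- if (is.null(mod$CCA)) numeric(0) else mod$CCA$eig * k
  eig_u <- if (is.null(mod$CA)) numeric(0) else mod$CA$eig * k
  tot <- sum(eig_c[eig_c > 0]) + sum(eig_u[eig_u > 0])
  con <- sum(eig_c[eig_c > 0])
  res <- sum(eig_u[eig_u > 0])
  scores <- NULL
  if (length(eig_c) > 0) {
    scores <- vegan::scores(mod, display = "sites",
                            choices = seq_along(eig_c))
    colnames(scores) <- paste0("CAP", seq_len(ncol(scores)))
  }
  structure(list(model = mod, terms = terms,
                 eig_constrained = eig_c, eig_unconstrained = eig_u,
                 total_inertia = tot, constrained_inertia = con,
                 residual_inertia = res,
                 prop_explained = if (tot > 0) con / tot else 0,
                 site_scores = scores),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat("db-RDA:", if (length(x$terms)) paste(x$terms, collapse = " + ") else
    "(unconstrained)", "\n")
  cat(sprintf("inertia: total %.4f, constrained %.4f (%.1f%%), residual %.4f\n",
              x$total_inertia, x$constrained_inertia,
              100 * x$prop_explained, x$residual_inertia))
  invisible(x)
}

#' Permutation tests for db-RDA
#'
#' Pseudo-F permutation tests of the constrained ordination: `overall` tests
#' the full constraint set with free permutation of samples; `margin` tests
#' each term with all other terms retained (permuting residuals of the
#' reduced model); `axis` tests the CAP axes sequentially. P-values use the
#' `(1 + hits) / (1 + n_perm)` convention and can never be exactly zero.
#'
#' @param d Dissimilarities (`dist` or symmetric matrix).
#' @param meta Imputed metadata.
#' @param terms Constraint terms.
#' @param n_perm Number of permutations (default 9999, as in standard
#'   ecological practice).
#' @param scope `"margin"` (default), `"overall"` or `"axis"`.
#' @param seed Integer seed for the permutation stream.
#' @return Data frame with columns `term`, `df`, `ss`, `statistic`
#'   (pseudo-F) and `p`.
#' @export
dbrda_permtest <- function(d, meta, terms = c("status", "age", "gender", "bcs"),
                           n_perm = 9999, scope = c("margin", "overall", "axis"),
                           seed = 1) {
  scope <- match.arg(scope)
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (length(terms) == 0) stop("permutation tests need at least one term")
  fit <- dbrda_fit(d, meta, terms)
  set.seed(seed)
  by <- switch(scope, overall = NULL, margin = "margin", axis = "axis")
  tab <- stats::anova(fit$model, permutations = n_perm, by = by)
  ss_col <- intersect(c("SumOfSqs", "Variance"), colnames(tab))[1]
  data.frame(term = rownames(tab), df = tab$Df, ss = tab[[ss_col]],
             statistic = tab$F, p = tab$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}
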