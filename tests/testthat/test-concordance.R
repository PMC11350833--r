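test_that("vectorised Welch screen matches t.test per OTU", {
  x <- random_counts(20, 40, seed = 41)
  meta <- toy_metadata(8, 6, 6, seed = 42)
  ctrl <- which(meta$status == "control")
  surv <- which(meta$status == "survey_ibd")
  res <- equibiome:::welch_t_columns(x, ctrl, surv)
  for (j in sample(ncol(x), 10)) {
    ref <- t.test(x[ctrl, j], x[surv, j])
    expect_equal(res$statistic[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df[j], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
  }
  # degenerate: identical constant columns are never candidates
  x[, 1] <- 5L
  expect_false("otu001" %in% screen_candidates(x, meta))
})

test_that("candidate screen keeps separated OTUs and respects the null rate", {
  meta <- toy_metadata(5, 5, 5, seed = 43)
  x <- random_counts(15, 30, seed = 44)
  x[, 1] <- c(rep(0L, 5), rep(60L, 5), rep(55L, 5))  # complete separation
  expect_true("otu001" %in% screen_candidates(x, meta))
  # under the null the selected fraction is near alpha * 2 (two comparisons)
  meta2 <- toy_metadata(10, 10, 10, seed = 45)
  x2 <- random_counts(30, 2000, seed = 46)
  frac <- length(screen_candidates(x2, meta2)) / 2000
  expect_lt(abs(frac - 0.0975), 0.025)
})

test_that("mean differences and the consistency statistic follow arithmetic", {
  x <- rbind(a1 = c(1, 4), a2 = c(3, 8), b1 = c(2, 0), b2 = c(4, 2))
  colnames(x) <- c("u", "v")
  d <- mean_difference(x, c("a1", "a2"), c("b1", "b2"), c("u", "v"))
  expect_equal(unname(d), c(-1, 5))
  expect_equal(mean_difference(x, c("b1", "b2"), c("a1", "a2"), c("u", "v")), -d)
  expect_error(mean_difference(x, "a1", "a1", "u"), "overlap")
  expect_error(mean_difference(x, "a1", "b1", character(0)), "empty candidate")
  expect_equal(consistency_stat(1:4, 1:4), 1)
  expect_equal(consistency_stat(1:4, -(1:4)), -1)
  expect_equal(consistency_stat(c(1, 2, 3, 5), c(2, 1, 4, 6)),
               cor(c(1, 2, 3, 5), c(2, 1, 4, 6)))
  expect_error(consistency_stat(c(1, 1, 1), c(1, 2, 3)), "first")
})

test_that("split-control bootstrap recovers strong concordance and is seeded", {
  coh <- small_cohort("strong", seed = 51)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 52)
  rb <- bootstrap_consistency(r, coh$metadata, n_boot = 40, seed = 53)
  expect_gt(mean(rb), 0.8)
  expect_identical(bootstrap_consistency(r, coh$metadata, n_boot = 40, seed = 53), rb)
  expect_true(all(abs(rb) <= 1))
  expect_error(bootstrap_consistency(r, coh$metadata[0, ], n_boot = 2), "nrow")
})

test_that("permutation null is centred, seeded, and propagates selection", {
  coh <- small_cohort("null", seed = 54)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 55)
  rp <- permutation_null(r, coh$metadata, n_perm = 60, seed = 56)
  expect_identical(permutation_null(r, coh$metadata, n_perm = 60, seed = 56), rp)
  # re-screening inside each permutation propagates the selection-induced
  # positive correlation (the bias the null exists to capture) ...
  expect_gt(mean(rp), 0)
  # ... whereas a fixed candidate set gives a null centred near zero
  cand_fixed <- screen_candidates(r, coh$metadata)
  rp_fixed <- permutation_null(r, coh$metadata, n_perm = 60, seed = 58,
                               candidates = cand_fixed)
  expect_lt(abs(mean(rp_fixed)), 0.15)
  # selection-induced bias: the implementation matches a plain re-implementation
  set.seed(57)
  brute <- numeric(40)
  meta <- coh$metadata
  for (i in 1:40) {
    pm <- meta
    pm$status <- sample(meta$status)
    cand <- screen_candidates(r, pm, 0.05)
    ctrl <- which(pm$status == "control")
    c1 <- sample(ctrl, floor(length(ctrl) / 2))
    c2 <- setdiff(ctrl, c1)
    d1 <- colMeans(r[c1, cand, drop = FALSE]) -
      colMeans(r[pm$status == "survey_ibd", cand, drop = FALSE])
    d2 <- colMeans(r[c2, cand, drop = FALSE]) -
      colMeans(r[pm$status == "acute_ibd", cand, drop = FALSE])
    brute[i] <- cor(d1, d2)
  }
  expect_lt(abs(mean(rp) - mean(brute)),
            3 * sqrt(sd(rp)^2 / length(rp) + sd(brute)^2 / 40))
})

test_that("distribution comparison reduces to the Welch formulas", {
  expect_equal(compare_dists(c(1, 1, 1, 1) + 1e-9 * (1:4), c(1, 1, 1, 1) + 1e-9 * (4:1))$p,
               1, tolerance = 1e-2)
  set.seed(61)
  a <- rnorm(30, 0.4, 0.05); b <- rnorm(40, 0, 0.1)
  got <- compare_dists(a, b)
  o <- oracle_welch(a, b)
  expect_equal(got$statistic, o$statistic, tolerance = 1e-12)
  expect_equal(got$df, o$df, tolerance = 1e-10)
  expect_equal(got$p, o$p, tolerance = 1e-12)
  expect_gt(abs(compare_dists(rep(0, 20) + rnorm(20, sd = 1e-6), rep(1, 20))$statistic), 100)
})

test_that("concordance_test is reproducible bit-for-bit from one seed", {
  coh <- small_cohort(seed = 62)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 63)
  res1 <- concordance_test(r, coh$metadata, n_boot = 20, n_perm = 20, seed = 64)
  res2 <- concordance_test(r, coh$metadata, n_boot = 20, n_perm = 20, seed = 64)
  expect_identical(res1, res2)
  expect_true(all(abs(res1$r_boot) <= 1) && all(abs(res1$r_null) <= 1))
  expect_true(res1$test$df > 0)
})

test_that("sign-agreement enrichment reproduces the hand 2x2 computation", {
  coh <- small_cohort(seed = 65)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 66)
  da <- intersect(coh$truth$da_ids, colnames(r))
  res <- sign_agreement_test(r, coh$metadata, da)
  expect_equal(unname(res$statistic), oracle_yates_chisq(res$observed),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$consistent_fraction,
               res$observed["da", "consistent"] / sum(res$observed["da", ]))
  # the hand-checked table: [[30,5],[50,50]] with Yates correction
  expect_equal(oracle_yates_chisq(rbind(c(30, 5), c(50, 50))),
               unname(chisq.test(rbind(c(30, 5), c(50, 50)))$statistic),
               tolerance = 1e-10)
  expect_equal(30 / 35, 0.857, tolerance = 1e-3)
})

test_that("F/B count enrichment matches the goodness-of-fit oracle", {
  ids <- sprintf("o%03d", 1:370)
  tax <- taxonomy_table(ids, c(rep("d__B;p__Firmicutes", 270),
                               rep("d__B;p__Bacteroidota", 100)))
  da <- c(ids[1:12], ids[271:290])  # 12 F, 20 B
  res <- fb_count_enrichment(da, ids, tax)
  expect_equal(unname(res$expected), c(32 * 270 / 370, 32 * 100 / 370),
               tolerance = 1e-10)
  expect_equal(unname(res$statistic),
               oracle_gof_chisq(c(12, 20), c(270, 100)), tolerance = 1e-10)
  expect_equal(res$statistic, 20.4, tolerance = 0.01)
  expect_equal(res$universe_ratio, 2.7)
  expect_equal(res$da_ratio, 0.6)
  # ratio-matched DA set gives chi-squared 0
  da0 <- c(ids[1:27], ids[271:280])
  expect_equal(fb_count_enrichment(da0, ids, tax)$statistic, 0, tolerance = 1e-10)
  # symmetric in phylum order
  tax_r <- taxonomy_table(ids, c(rep("d__B;p__Bacteroidota", 270),
                                 rep("d__B;p__Firmicutes", 100)))
  res_r <- fb_count_enrichment(da, ids, tax_r)
  expect_equal(res_r$statistic, res$statistic, tolerance = 1e-10)
})
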