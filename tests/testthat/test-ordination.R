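test_that("Jaccard distances honour set-count and boundary identities", {
  x <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1), c = c(1, 1, 1, 0),
             d = c(0, 0, 0, 5))
  db <- as.matrix(jaccard_matrix(x, binary = TRUE))
  expect_equal(db["a", "c"], 0)           # identical presence sets
  expect_equal(db["a", "d"], 1)           # disjoint presence sets
  expect_equal(db["a", "b"], 1 - 2 / 4)   # {1,2,3} vs {2,3,4}
  # quantitative form is 2B/(1+B)
  y <- random_counts(6, 12, seed = 21)
  b <- vegan::vegdist(y, "bray")
  expect_equal(as.vector(jaccard_matrix(y)), as.vector(2 * b / (1 + b)),
               tolerance = 1e-12)
  expect_true(all(as.vector(jaccard_matrix(y)) >= 0 &
                  as.vector(jaccard_matrix(y)) <= 1))
})

test_that("all-zero samples get defined distances with a warning", {
  x <- rbind(a = c(1, 2, 0), b = c(0, 0, 0), c = c(0, 0, 0))
  expect_warning(d <- jaccard_matrix(x), "all-zero")
  m <- as.matrix(d)
  expect_equal(m["b", "c"], 0)
  expect_equal(m["a", "b"], 1)
})

test_that("unconstrained db-RDA equals principal-coordinates analysis", {
  x <- random_counts(10, 25, seed = 31)
  d <- jaccard_matrix(x)
  fit <- dbrda_fit(d, meta = data.frame(row.names = rownames(x)), terms = character(0))
  pcoa <- cmdscale(d, k = 9, eig = TRUE)
  pos <- pcoa$eig[pcoa$eig > 1e-8] / (nrow(x) - 1)
  expect_equal(unname(fit$eig_unconstrained[seq_along(pos)]), pos,
               tolerance = 1e-8)
  expect_equal(fit$constrained_inertia, 0)
  expect_equal(fit$prop_explained, 0)
})

test_that("db-RDA on Euclidean distances reproduces direct RDA", {
  set.seed(41)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6), paste0("v", 1:4)))
  meta <- data.frame(a = rnorm(6), g = factor(rep(c("u", "v"), 3)))
  fit <- dbrda_fit(dist(x), meta, terms = c("a", "g"))
  ref <- vegan::rda(x ~ a + g, data = meta)
  expect_equal(unname(fit$eig_constrained), unname(ref$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
  # decomposition closes
  expect_equal(fit$constrained_inertia + fit$residual_inertia,
               fit$total_inertia, tolerance = 1e-8)
})

test_that("db-RDA inertia is invariant to reordering and distance scaling", {
  coh <- small_cohort(seed = 6)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 7)
  meta <- impute_metadata(coh$metadata)
  d <- jaccard_matrix(r)
  fit <- dbrda_fit(d, meta, terms = c("status", "age"))
  # scaling all distances by a constant leaves the proportion unchanged
  fit2 <- dbrda_fit(as.dist(as.matrix(d) * 3), meta, terms = c("status", "age"))
  expect_equal(fit$prop_explained, fit2$prop_explained, tolerance = 1e-10)
  # joint reordering of samples and metadata
  idx <- sample(nrow(meta))
  d3 <- as.dist(as.matrix(d)[idx, idx])
  fit3 <- dbrda_fit(d3, meta[idx, ], terms = c("status", "age"))
  expect_equal(fit3$prop_explained, fit$prop_explained, tolerance = 1e-10)
  expect_true(fit$total_inertia >= 0 && fit$prop_explained >= 0 &&
              fit$prop_explained <= 1)
})

test_that("permutation test saturates on strong structure and is seeded", {
  set.seed(51)
  x <- rbind(matrix(rnorm(60, 0), 10), matrix(rnorm(60, 8), 10))
  rownames(x) <- paste0("s", 1:20)
  meta <- data.frame(grp = factor(rep(c("a", "b"), each = 10)))
  pt <- dbrda_permtest(dist(x), meta, terms = "grp", n_perm = 199,
                       scope = "overall", seed = 3)
  expect_equal(pt$p[1], 1 / 200)  # minimum attainable p
  pt2 <- dbrda_permtest(dist(x), meta, terms = "grp", n_perm = 199,
                        scope = "overall", seed = 3)
  expect_identical(pt, pt2)
  expect_error(dbrda_permtest(dist(x), meta, terms = "grp", n_perm = 0), "at least 1")
})

test_that("margin and axis scopes report each term and axis", {
  coh <- small_cohort(seed = 16)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 17)
  meta <- impute_metadata(coh$metadata)
  d <- jaccard_matrix(r)
  pm <- dbrda_permtest(d, meta, n_perm = 99, scope = "margin", seed = 5)
  expect_setequal(setdiff(pm$term, "Residual"),
                  c("status", "age", "gender", "bcs"))
  pa <- dbrda_permtest(d, meta, n_perm = 99, scope = "axis", seed = 5)
  expect_true(all(grepl("^dbRDA|^Residual", pa$term)))
  ok <- !is.na(pm$p)
  expect_true(all(pm$p[ok] >= 1 / 100 & pm$p[ok] <= 1))
})
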