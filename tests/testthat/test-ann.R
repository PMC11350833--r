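test_that("rank-sum feature screen matches exact enumeration on small groups", {
  # complete separation, 4 vs 4: exact two-sided p = 2/70
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  expect_equal(oracle_ranksum_exact(a, b), 2 / 70, tolerance = 1e-12)
  # normal-approximation p agrees with wilcox.test on random ties-free data
  set.seed(71)
  for (i in 1:50) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    v <- rnorm(n1 + n2)
    labels <- rep(c(1, 0), c(n1, n2))
    p_pkg <- equibiome:::rank_sum_p(cbind(v), labels)
    ref <- wilcox.test(v[labels == 1], v[labels == 0],
                       exact = FALSE, correct = TRUE)
    expect_equal(p_pkg, ref$p.value, tolerance = 1e-10)
  }
  # tied data exercise the tie-corrected variance
  set.seed(72)
  for (i in 1:30) {
    v <- sample(0:3, 20, replace = TRUE)
    labels <- rep(c(1, 0), each = 10)
    p_pkg <- equibiome:::rank_sum_p(cbind(v), labels)
    ref <- suppressWarnings(wilcox.test(v[labels == 1], v[labels == 0],
                                        exact = FALSE, correct = TRUE))
    expect_equal(p_pkg, ref$p.value, tolerance = 1e-10)
  }
})

test_that("feature selection truncates, orders, and drops constants", {
  set.seed(73)
  x <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(NULL, sprintf("f%02d", 1:60)))
  labels <- rep(c(1, 0), each = 20)
  x[, 1:30] <- x[, 1:30] + rep(labels, 30) * 3  # strong signal in f01..f30
  x[, 60] <- 7  # constant
  sel <- select_features(x, labels, k = 10, alpha = 0.05)
  expect_length(sel, 10)
  expect_true(all(sel %in% sprintf("f%02d", 1:30)))
  expect_false("f60" %in% select_features(x, labels, k = 60, alpha = 0.05))
  p <- equibiome:::rank_sum_p(x, labels)
  expect_equal(sel, colnames(x)[order(p)[1:10]])
  expect_error(select_features(x[, 55:60, drop = FALSE], labels, alpha = 1e-12),
               "fewer than 2")
})

test_that("standardisation centres, scales, and replays stored constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize(x)
  expect_equal(unname(s$x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(s$x[, "b"]), c(0, 0, 0))  # constant column, scale 1
  expect_equal(unname(s$constants$scale[["b"]]), 1)
  expect_equal(standardize(x, s$constants)$x, s$x)
})

test_that("stratified splitting and class weights balance the classes", {
  labels <- rep(c(1, 0), c(10, 10))
  sp <- split_samples(labels, 0.8, seed = 74)
  expect_length(sp$train, 16)
  expect_equal(sum(labels[sp$train]), 8)
  expect_setequal(c(sp$train, sp$test), 1:20)
  expect_identical(split_samples(labels, 0.8, seed = 74), sp)
  w <- class_weights(rep(c(1, 0), c(30, 10)))
  expect_equal(unique(w), c(2 / 3, 2))
  expect_equal(sum(w[1:30]), sum(w[31:40]))
  expect_equal(sum(w), 40)
  expect_error(split_samples(c(1, 0, 0, 0), 0.8), "fewer than 2")
})

test_that("the network fits separable data and respects the penalty limit", {
  # 1-D separable toy, size 1, no decay
  x <- standardize(cbind(f = c(-3, -2, -1, 1, 2, 3)))$x
  y <- c(0, 0, 0, 1, 1, 1)
  mod <- train_ann(x, y, size = 1, decay = 0, seed = 75)
  expect_equal(as.integer(equibiome:::ann_forward(mod, x)$p > 0.5), y)
  # XOR needs the hidden layer; at least one of 10 restarts must solve it
  xx <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1)) * 2 - 1
  yy <- c(0, 1, 1, 0)
  solved <- any(vapply(1:10, function(s) {
    m <- train_ann(xx, yy, size = 2, decay = 0.001, seed = s, max_iter = 2000)
    all(as.integer(equibiome:::ann_forward(m, xx)$p > 0.5) == yy)
  }, logical(1)))
  expect_true(solved)
  # huge decay shrinks the weights towards zero and p towards the prior
  y2 <- rep(c(0, 1), 3)
  m_big <- train_ann(x, y2, size = 3, decay = 1e6, seed = 76)
  expect_lt(max(abs(m_big$w1)), 1e-2)
  expect_equal(unname(equibiome:::ann_forward(m_big, x)$p), rep(0.5, 6),
               tolerance = 0.02)
})

test_that("with no hidden structure the network tracks weighted logistic regression", {
  set.seed(77)
  x <- standardize(matrix(rnorm(200 * 2), 200, 2,
                          dimnames = list(NULL, c("a", "b"))))$x
  y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(200, sd = 0.8) > 0)
  w <- class_weights(y)
  mod <- train_ann(x, y, w, size = 1, decay = 0, seed = 78, max_iter = 5000,
                   tol = 1e-12)
  glm_fit <- suppressWarnings(glm(y ~ a + b, data = data.frame(x, y = y),
                                  family = binomial, weights = w))
  # a size-1 logistic network composes two logistics, so only the decision
  # boundary (the input-weight direction) is comparable, and the composed
  # likelihood peaks at a slightly different direction than a single logistic
  expect_equal(mod$w1[1, 1] / mod$w1[1, 2],
               coef(glm_fit)[["a"]] / coef(glm_fit)[["b"]], tolerance = 0.1)
  # and predictions agree in class
  p_ann <- equibiome:::ann_forward(mod, x)$p
  p_glm <- predict(glm_fit, type = "response")
  expect_gt(mean((p_ann > 0.5) == (p_glm > 0.5)), 0.95)
})

test_that("Cohen's kappa and confusion summaries follow their definitions", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  set.seed(79)
  for (i in 1:200) {
    pred <- sample(0:1, 20, replace = TRUE)
    obs <- sample(0:1, 20, replace = TRUE)
    expect_equal(cohens_kappa(pred, obs), oracle_kappa(pred, obs),
                 tolerance = 1e-12)
  }
  # confusion [[8,2],[1,9]] -> sensitivity 0.8, specificity 0.9
  cm <- list(w1 = matrix(1, 1, 1), b1 = 0, w2 = 1, b2 = 0)
  y <- rep(c(1, 0), each = 10)
  p <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 1), rep(0.1, 9))
  pred <- as.integer(p > 0.5)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  expect_equal(tp / sum(y), 0.8)
  expect_equal(tn / sum(!y), 0.9)
})

test_that("Garson importance matches the looped decomposition", {
  set.seed(80)
  for (i in 1:100) {
    h <- sample(2:5, 1); k <- sample(2:8, 1)
    mod <- structure(list(w1 = matrix(rnorm(h * k), h, k), b1 = rnorm(h),
                          w2 = rnorm(h), b2 = rnorm(1), features = NULL),
                     class = "ann_model")
    imp <- garson_importance(mod)
    expect_equal(unname(imp), oracle_garson(mod$w1, mod$w2), tolerance = 1e-12)
    expect_equal(sum(imp), 1, tolerance = 1e-12)
  }
  # symmetric two-feature network splits importance evenly
  mod2 <- structure(list(w1 = matrix(c(0.7, -0.7, -0.7, 0.7), 2, 2),
                         b1 = c(0, 0), w2 = c(1, 1), b2 = 0, features = NULL),
                    class = "ann_model")
  expect_equal(unname(garson_importance(mod2)), c(0.5, 0.5))
  mod1 <- structure(list(w1 = matrix(2, 1, 1), b1 = 0, w2 = 1.5, b2 = 0,
                         features = NULL), class = "ann_model")
  expect_equal(unname(garson_importance(mod1)), 1)
})

test_that("cross-validation finds chance on noise and perfection on signal", {
  set.seed(81)
  cfg <- ann_config(hidden = 3, decay = c(0.1, 0.3), repeats = 2, folds = 4,
                    max_iter = 200, seed = 82)
  # pure noise: accuracy near the majority-class prior
  xn <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(NULL, paste0("f", 1:10)))
  yn <- rep(c(1, 0), c(24, 16))
  cvn <- cross_validate(xn, yn, class_weights(yn), cfg)
  expect_lt(abs(cvn$best$mean_accuracy - 0.6), 0.22)
  # separable signal: near-perfect accuracy
  xs <- xn; xs[, 1] <- xs[, 1] + yn * 6
  cvs <- cross_validate(xs, yn, class_weights(yn), cfg)
  expect_gt(cvs$best$mean_accuracy, 0.95)
  expect_true(all(cvs$grid$mean_accuracy >= 0 & cvs$grid$mean_accuracy <= 1))
  expect_true(all(cvs$grid$sd_accuracy >= 0))
})

test_that("held-out evaluation applies stored scaling and flags missing features", {
  coh <- small_cohort("strong", seed = 83)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 84)
  cfg <- ann_config(hidden = 3, decay = 0.2, repeats = 2, folds = 3,
                    max_features = 50, max_iter = 200, seed = 85)
  res <- screen_ibd(r, coh$metadata, cfg)
  ev <- res$evaluation
  expect_equal(ev$sensitivity, ev$confusion["ibd", "ibd"] /
                 sum(ev$confusion[, "ibd"]))
  expect_equal(ev$specificity, ev$confusion["control", "control"] /
                 sum(ev$confusion[, "control"]))
  expect_true(all(ev$probabilities$p_ibd > 0 & ev$probabilities$p_ibd < 1))
  expect_error(predict(res$model, r[, 1:3]), "missing from prediction")
  # prediction is invariant to feature order
  xt <- r[res$split$test, , drop = FALSE]
  expect_equal(predict(res$model, xt[, rev(colnames(xt))]),
               predict(res$model, xt))
})

test_that("the screening pipeline is reproducible and leak-resistant", {
  coh <- small_cohort("strong", seed = 86)
  r <- rarefy(filter_rare_otus(coh$counts), seed = 87)
  cfg <- ann_config(hidden = 3, decay = 0.2, repeats = 2, folds = 3,
                    max_features = 40, max_iter = 150, seed = 88)
  res1 <- screen_ibd(r, coh$metadata, cfg)
  res2 <- screen_ibd(r, coh$metadata, cfg)
  expect_identical(res1$cv$grid, res2$cv$grid)
  expect_identical(res1$model$w1, res2$model$w1)
  expect_identical(res1$evaluation$probabilities, res2$evaluation$probabilities)
  # label permutation: held-out accuracy near the class prior (leakage
  # guard on the untouched test split; CV accuracy is expected to carry
  # selection optimism because features are screened before CV)
  accs <- vapply(1:3, function(i) {
    meta_perm <- coh$metadata
    set.seed(88 + i)
    meta_perm$status <- sample(meta_perm$status)
    screen_ibd(r, meta_perm, cfg)$evaluation$accuracy
  }, numeric(1))
  prior <- max(mean(coh$metadata$status != "control"),
               mean(coh$metadata$status == "control"))
  n_test <- length(screen_ibd(r, coh$metadata, cfg)$split$test)
  bound <- 2.6 * sqrt(prior * (1 - prior) / n_test) / sqrt(3)
  expect_lt(mean(accs) - prior, bound)
})
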