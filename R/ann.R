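#' Configuration for the neural-network screening model
#'
#' Defaults follow common practice for shallow diagnostic models on
#' microbiome counts: a small hidden-size grid, moderate weight decay, five
#' repeats of five stratified folds, and at most 200 features selected by
#' rank-sum screening at p < 0.05.
#'
#' @param hidden Hidden-layer sizes to try.
#' @param decay Weight-decay (L2 penalty) values to try.
#' @param repeats,folds Repeated stratified k-fold CV layout.
#' @param max_features Maximum number of OTU features kept.
#' @param select_alpha Rank-sum p-value threshold for feature selection.
#' @param train_frac Fraction of samples in the training split.
#' @param max_iter,tol Optimiser iteration cap and convergence tolerance.
#' @param seed Integer seed driving the whole pipeline.
#' @return List of class `ann_config`.
#' @export
ann_config <- function(hidden = c(3, 6, 9), decay = c(0.1, 0.2, 0.3, 0.4),
                       repeats = 5, folds = 5, max_features = 200,
                       select_alpha = 0.05, train_frac = 0.8,
                       max_iter = 500, tol = 1e-8, seed = 1) {
  stopifnot(folds >= 2, train_frac > 0, train_frac < 1, all(decay >= 0),
            all(hidden >= 1))
  structure(list(hidden = hidden, decay = decay, repeats = repeats,
                 folds = folds, max_features = max_features,
                 select_alpha = select_alpha, train_frac = train_frac,
                 max_iter = max_iter, tol = tol, seed = seed),
            class = "ann_config")
}

#' Rank-sum p-values over matrix columns
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test per column, using the
#' normal approximation with tie correction and continuity correction.
#' Constant columns get p = 1.
#'
#' @param x Samples x features matrix.
#' @param labels Logical or 0/1 vector splitting the rows into two groups.
#' @return Numeric vector of two-sided p-values, one per column.
#' @keywords internal
rank_sum_p <- function(x, labels) {
  g1 <- as.logical(labels)
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both classes must be present")
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    rk <- rank(v)
    u <- sum(rk[g1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (u - n1 * n2 / 2)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

#' Select informative OTU features
#'
#' Ranks OTUs by the two-sample rank-sum p-value (IBD vs control), keeps
#' those below `alpha`, and truncates to the `k` most significant.
#'
#' @param counts Samples x OTUs count matrix (training samples only, to avoid
#'   test-set leakage).
#' @param labels Binary class labels aligned with rows (1 = IBD).
#' @param k Maximum number of features (default 200).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of selected OTU ids, ordered by ascending p.
#' @export
select_features <- function(counts, labels, k = 200, alpha = 0.05) {
  p <- rank_sum_p(counts, labels)
  ord <- order(p)
  sel <- ord[p[ord] < alpha]
  if (length(sel) < 2)
    stop("fewer than 2 features pass the screen; consider raising alpha")
  colnames(counts)[utils::head(sel, k)]
}

#' Column-wise standardisation
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Zero-variance columns are centred and given scale 1.
#' The constants are returned for reuse on prediction data.
#'
#' @param x Samples x features matrix.
#' @param constants Optional list with `center` and `scale` from a previous
#'   call, to apply a stored transformation.
#' @return List with `x` (scaled matrix) and `constants`.
#' @export
standardize <- function(x, constants = NULL) {
  if (is.null(constants)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    constants <- list(center = ctr, scale = scl)
  }
  xs <- sweep(sweep(x, 2, constants$center, "-"), 2, constants$scale, "/")
  list(x = xs, constants = constants)
}

#' Stratified train/test split
#'
#' @param labels Binary class labels (each class needs >= 2 samples).
#' @param fraction Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_samples <- function(labels, fraction = 0.8, seed = 1) {
  set.seed(seed)
  idx <- seq_along(labels)
  train <- integer(0)
  for (cl in unique(labels)) {
    members <- idx[labels == cl]
    if (length(members) < 2) stop("class '", cl, "' has fewer than 2 samples")
    train <- c(train, sample(members, round(length(members) * fraction)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(idx, train))
}

#' Class-balancing sample weights
#'
#' \eqn{w_i = N / (2 N_{class(i)})}: the weights sum to N and each class
#' carries equal total weight.
#'
#' @param labels Binary class labels.
#' @return Numeric weight per sample.
#' @export
class_weights <- function(labels) {
  n <- length(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("expected exactly 2 classes")
  unname(n / (2 * tab[as.character(labels)]))
}

ann_unpack <- function(par, k, h) {
  w1 <- matrix(par[seq_len(h * k)], h, k)
  b1 <- par[h * k + seq_len(h)]
  w2 <- par[h * k + h + seq_len(h)]
  b2 <- par[h * k + 2 * h + 1]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

ann_forward <- function(w, x) {
  a <- sweep(x %*% t(w$w1), 2, w$b1, "+")
  h <- sigmoid(a)
  p <- sigmoid(drop(h %*% w$w2) + w$b2)
  list(hidden = h, p = p)
}

#' Train the single-hidden-layer logistic network
#'
#' Model: \eqn{p(x) = \sigma(w_2 \cdot \sigma(W_1 x + b_1) + b_2)} with the
#' logistic activation throughout. Minimises the weighted cross-entropy plus
#' an L2 penalty `decay` on all weights and biases, by quasi-Newton
#' (L-BFGS-B) optimisation with an analytic gradient, starting from small
#' uniform random weights in \eqn{[-0.5, 0.5]}.
#'
#' @param x Standardised samples x features matrix.
#' @param y Binary 0/1 labels (1 = positive class).
#' @param weights Per-sample weights (see [class_weights()]); default 1.
#' @param size Hidden-layer size.
#' @param decay L2 penalty coefficient.
#' @param seed Integer seed for the weight initialisation (NULL to use the
#'   current RNG state).
#' @param max_iter Optimiser iteration cap.
#' @param tol Convergence tolerance (projected-gradient).
#' @param constants Optional standardisation constants to store with the
#'   model for later prediction on raw data.
#' @param features Optional feature-id vector to store with the model.
#' @return List of class `ann_model` with the weight matrices, training
#'   configuration, and any stored `constants`/`features`.
#' @export
train_ann <- function(x, y, weights = rep(1, length(y)), size = 3, decay = 0.1,
                      seed = NULL, max_iter = 500, tol = 1e-8,
                      constants = NULL, features = colnames(x)) {
  stopifnot(size >= 1, nrow(x) == length(y), all(y %in% c(0, 1)))
  k <- ncol(x)
  h <- size
  npar <- h * k + 2 * h + 1
  if (!is.null(seed)) set.seed(seed)
  par0 <- stats::runif(npar, -0.5, 0.5)
  eps <- 1e-12
  fn <- function(par) {
    w <- ann_unpack(par, k, h)
    p <- ann_forward(w, x)$p
    ce <- -sum(weights * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
    ce + decay * sum(par^2)
  }
  gr <- function(par) {
    w <- ann_unpack(par, k, h)
    fwd <- ann_forward(w, x)
    g_eta <- weights * (fwd$p - y)                  # n
    g_w2 <- drop(crossprod(fwd$hidden, g_eta))     # h
    g_b2 <- sum(g_eta)
    g_a <- (g_eta %o% w$w2) * fwd$hidden * (1 - fwd$hidden)  # n x h
    g_w1 <- crossprod(g_a, x)                      # h x k
    g_b1 <- colSums(g_a)
    c(as.vector(g_w1), g_b1, g_w2, g_b2) + 2 * decay * par
  }
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter,
                                     pgtol = tol,
                                     factr = 1e7))
  if (!is.finite(opt$value))
    stop("non-finite loss after optimisation (value = ", opt$value, ")")
  w <- ann_unpack(opt$par, k, h)
  structure(list(w1 = w$w1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 size = size, decay = decay, loss = opt$value,
                 converged = opt$convergence == 0,
                 features = features, constants = constants),
            class = "ann_model")
}

#' Predict IBD probabilities from a trained network
#'
#' @param object An `ann_model`.
#' @param newdata Samples x features matrix. If the model stores
#'   standardisation constants the data are taken as raw and scaled here;
#'   columns are matched to the stored feature ids when present.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive (IBD) class.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) {
    missing_feats <- setdiff(object$features, colnames(x))
    if (length(missing_feats) > 0)
      stop("feature id(s) missing from prediction data: ",
           paste(utils::head(missing_feats, 10), collapse = ", "))
    x <- x[, object$features, drop = FALSE]
  }
  if (!is.null(object$constants)) x <- standardize(x, object$constants)$x
  ann_forward(object, x)$p
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("single-hidden-layer logistic network: %d features, size %d, decay %g\n",
              ncol(x$w1), x$size, x$decay))
  invisible(x)
}

#' Cohen's kappa for binary predictions
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)}; 0 when the
#' expected agreement is already perfect.
#'
#' @param pred,obs Binary vectors of predicted and observed classes.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  n <- length(obs)
  po <- mean(pred == obs)
  classes <- union(unique(pred), unique(obs))
  pe <- sum(vapply(classes, function(cl)
    mean(pred == cl) * mean(obs == cl), numeric(1)))
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    members <- sample(which(y == cl))
    fold[members] <- rep_len(seq_len(k), length(members))
  }
  fold
}

#' Grid search by repeated stratified k-fold cross-validation
#'
#' For every (size, decay) combination, runs `repeats` x `folds` stratified
#' CV on the training data: the network is fitted on the fold-train part
#' (standardisation constants recomputed within the fold-train) and
#' evaluated on the held fold at threshold 0.5. Reports mean and SD of fold
#' accuracy and Cohen's kappa. The best configuration has the highest mean
#' accuracy; ties break to the smaller size, then the larger decay (the more
#' regularised model).
#'
#' @param x Training samples x selected features matrix (raw, unscaled).
#' @param y Binary 0/1 labels.
#' @param weights Per-sample weights.
#' @param config An [ann_config()].
#' @return List of class `cv_result` with `grid` (per-configuration summary
#'   data frame) and `best` (row of the best configuration).
#' @export
cross_validate <- function(x, y, weights = class_weights(y), config = ann_config()) {
  set.seed(config$seed)
  grid <- expand.grid(size = config$hidden, decay = config$decay)
  acc <- matrix(NA_real_, nrow(grid), config$repeats * config$folds)
  kap <- matrix(NA_real_, nrow(grid), config$repeats * config$folds)
  col <- 0
  for (rep_i in seq_len(config$repeats)) {
    repeat {  # redraw folds if a held fold ends up single-class
      fold <- stratified_folds(y, config$folds)
      ok <- all(vapply(seq_len(config$folds), function(f)
        length(unique(y[fold == f])) == 2, logical(1)))
      if (ok) break
    }
    for (f in seq_len(config$folds)) {
      col <- col + 1
      tr <- fold != f
      std <- standardize(x[tr, , drop = FALSE])
      xte <- standardize(x[!tr, , drop = FALSE], std$constants)$x
      for (gi in seq_len(nrow(grid))) {
        mod <- train_ann(std$x, y[tr], weights[tr], size = grid$size[gi],
                         decay = grid$decay[gi], max_iter = config$max_iter,
                         tol = config$tol)
        pred <- as.integer(ann_forward(mod, xte)$p > 0.5)
        acc[gi, col] <- mean(pred == y[!tr])
        kap[gi, col] <- cohens_kappa(pred, y[!tr])
      }
    }
  }
  grid$mean_accuracy <- rowMeans(acc)
  grid$sd_accuracy <- apply(acc, 1, stats::sd)
  grid$mean_kappa <- rowMeans(kap)
  grid$sd_kappa <- apply(kap, 1, stats::sd)
  ord <- order(-grid$mean_accuracy, grid$size, -grid$decay)
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("repeated stratified CV grid search\n")
  print(x$grid, digits = 3)
  cat(sprintf("best: size %d, decay %g (mean accuracy %.3f)\n",
              x$best$size, x$best$decay, x$best$mean_accuracy))
  invisible(x)
}

#' Evaluate a trained model on held-out samples
#'
#' Applies the model's stored scaling constants to raw test counts, predicts
#' at threshold 0.5 and summarises the confusion matrix with IBD as the
#' positive class.
#'
#' @param model An `ann_model` with stored `features` and `constants`.
#' @param counts_test Raw samples x OTUs matrix for the test samples.
#' @param labels_test Binary 0/1 labels (1 = IBD).
#' @return List of class `eval_result`: `confusion` (2x2), `sensitivity`,
#'   `specificity`, `accuracy`, `probabilities` (per-sample data frame).
#' @export
evaluate_test <- function(model, counts_test, labels_test) {
  p <- predict(model, counts_test)
  pred <- as.integer(p > 0.5)
  tp <- sum(pred == 1 & labels_test == 1)
  fn <- sum(pred == 0 & labels_test == 1)
  tn <- sum(pred == 0 & labels_test == 0)
  fp <- sum(pred == 1 & labels_test == 0)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(predicted = c("ibd", "control"),
                                 truth = c("ibd", "control")))
  structure(list(confusion = conf,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(labels_test),
                 probabilities = data.frame(
                   sample_id = rownames(counts_test) %||% seq_along(p),
                   p_ibd = p, call = ifelse(pred == 1, "ibd", "control"),
                   truth = ifelse(labels_test == 1, "ibd", "control"),
                   stringsAsFactors = FALSE)),
            class = "eval_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_result <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Garson input-importance decomposition
#'
#' Distributes the output weight of each hidden node over the input features
#' in proportion to the absolute input-to-hidden weights:
#' \eqn{I_j = \sum_h \frac{|W1_{hj}|}{\sum_m |W1_{hm}|} |w2_h|}, normalised
#' to sum to 1. A closed-form, weight-based importance measure for
#' single-hidden-layer networks.
#'
#' @param model An `ann_model`.
#' @return Named numeric vector of importances summing to 1.
#' @export
garson_importance <- function(model) {
  aw1 <- abs(model$w1)                      # h x k
  share <- aw1 / rowSums(aw1)               # rows sum to 1
  imp <- drop(abs(model$w2) %*% share)      # k
  imp <- imp / sum(imp)
  names(imp) <- model$features %||% colnames(model$w1)
  imp
}

#' End-to-end IBD screening pipeline
#'
#' Merges the two IBD groups into the positive class, makes a stratified
#' 80/20 train/test split, selects features on the training split only
#' (rank-sum screen), grid-searches (size, decay) by repeated stratified CV
#' with class-balancing weights, refits the best configuration on the full
#' training split, and evaluates the untouched test split. Fully
#' reproducible from `config$seed`.
#'
#' @param counts Samples x OTUs (rarefied) count matrix.
#' @param meta Metadata aligned with `counts` (`status` used).
#' @param config An [ann_config()].
#' @return List of class `screen_result`: `split`, `features`, `cv`,
#'   `model`, `evaluation`, `importance`, `labels`.
#' @export
screen_ibd <- function(counts, meta, config = ann_config()) {
  stopifnot(nrow(meta) == nrow(counts))
  y <- as.integer(meta$status %in% c("survey_ibd", "acute_ibd"))
  split <- split_samples(y, fraction = config$train_frac, seed = config$seed)
  x_train <- counts[split$train, , drop = FALSE]
  y_train <- y[split$train]
  feats <- select_features(x_train, y_train, k = config$max_features,
                           alpha = config$select_alpha)
  w_train <- class_weights(y_train)
  cv <- cross_validate(x_train[, feats, drop = FALSE], y_train, w_train, config)
  std <- standardize(x_train[, feats, drop = FALSE])
  set.seed(config$seed + 1L)
  model <- train_ann(std$x, y_train, w_train, size = cv$best$size,
                     decay = cv$best$decay, max_iter = config$max_iter,
                     tol = config$tol, constants = std$constants,
                     features = feats)
  evaluation <- evaluate_test(model, counts[split$test, , drop = FALSE],
                              y[split$test])
  structure(list(split = split, features = feats, cv = cv, model = model,
                 evaluation = evaluation,
                 importance = garson_importance(model), labels = y),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("IBD screen: %d features, best size %d / decay %g\n",
              length(x$features), x$cv$best$size, x$cv$best$decay))
  cat(sprintf("CV accuracy %.3f (SD %.3f), kappa %.3f (SD %.3f)\n",
              x$cv$best$mean_accuracy, x$cv$best$sd_accuracy,
              x$cv$best$mean_kappa, x$cv$best$sd_kappa))
  cat(sprintf("test sensitivity %.3f, specificity %.3f\n",
              x$evaluation$sensitivity, x$evaluation$specificity))
  invisible(x)
}
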