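#' @name evaluation
#' @title Stage 2: under-sampled, cross-validated SVM evaluation
#' @description
#' Evaluates cumulative feature-class subsets (A, AB, ..., A-E) with
#' soft-margin SVMs over a kernel/parameter grid: per stratified CV fold the
#' training portion is class-balanced by random under-sampling, z-scored
#' with training statistics, and an SVM is trained; sensitivity, specificity,
#' accuracy and AUC (apnea = positive class) are averaged across folds. The
#' hill-climb keeps the class subset with the greatest mean accuracy across
#' grid configurations, ties broken by the smaller accuracy spread.
NULL

#' Describe one SVM configuration
#' @param kernel "linear", "poly" or "rbf"
#' @param R regularization constant (> 0)
#' @param d polynomial degree (poly only)
#' @param sigma RBF width (rbf only); the kernel is
#'   `exp(-||x - y||^2 / (2 sigma^2))`
#' @return a `kernel_config` list
#' @export
kernel_config <- function(kernel = c("linear", "poly", "rbf"), R = 1,
                          d = NULL, sigma = NULL) {
  kernel <- match.arg(kernel)
  if (R <= 0) stop("R must be > 0")
  if (kernel == "poly" && (is.null(d) || d < 1)) {
    stop("polynomial kernel needs a degree d >= 1")
  }
  if (kernel == "rbf" && (is.null(sigma) || sigma <= 0)) {
    stop("RBF kernel needs sigma > 0")
  }
  structure(list(kernel = kernel, R = R, d = d, sigma = sigma),
            class = "kernel_config")
}

#' The default kernel/parameter grid
#'
#' RBF widths {1, 5, 25}, polynomial degrees {2, 3, 4} and regularization
#' {0.2, 1, 10}: 21 configurations.
#'
#' @param config pipeline configuration
#' @return list of [kernel_config()]s
#' @export
default_grid <- function(config = default_config()) {
  svm <- config$svm
  grid <- list()
  for (s in svm$sigma) for (R in svm$R) {
    grid[[length(grid) + 1L]] <- kernel_config("rbf", R, sigma = s)
  }
  for (d in svm$degree) for (R in svm$R) {
    grid[[length(grid) + 1L]] <- kernel_config("poly", R, d = d)
  }
  for (R in svm$R) {
    grid[[length(grid) + 1L]] <- kernel_config("linear", R)
  }
  grid
}

config_label <- function(cfg) {
  switch(cfg$kernel,
         linear = sprintf("Linear R=%g", cfg$R),
         poly = sprintf("Poly d=%d R=%g", cfg$d, cfg$R),
         rbf = sprintf("RBF sigma=%g R=%g", cfg$sigma, cfg$R))
}

#' Class-balance a labeled set by under-sampling the majority class
#'
#' Keeps every minority-class row and a seeded random subset (without
#' replacement) of the majority class of equal size.
#'
#' @param labels character/factor vector of "A"/"N" labels
#' @param seed RNG seed
#' @return integer row indices of the balanced subset (original order)
#' @export
undersample_idx <- function(labels, seed) {
  idx_a <- which(labels == "A")
  idx_n <- which(labels == "N")
  if (length(idx_a) == 0L || length(idx_n) == 0L) {
    stop("under-sampling needs both classes present")
  }
  set.seed(seed)
  if (length(idx_a) < length(idx_n)) {
    idx_n <- sort(sample(idx_n, length(idx_a)))
  } else if (length(idx_n) < length(idx_a)) {
    idx_a <- sort(sample(idx_a, length(idx_n)))
  }
  sort(c(idx_a, idx_n))
}

#' Under-sample a feature table to class balance
#' @param feature_table data.frame with a `label` column
#' @param seed RNG seed
#' @return the balanced subset of rows
#' @export
undersample <- function(feature_table, seed = 1L) {
  feature_table[undersample_idx(feature_table$label, seed), , drop = FALSE]
}

#' Fit a per-feature z-score transform on training data
#' @param X numeric training matrix (rows = epochs)
#' @return a `standardizer` with `center` and `scale` (zero-variance
#'   features get scale 1, i.e. are passed through centered)
#' @export
standardize_fit <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[!is.finite(sc) | sc == 0] <- 1
  structure(list(center = ctr, scale = sc), class = "standardizer")
}

#' Apply a fitted z-score transform
#' @param X numeric matrix
#' @param tf a `standardizer` from [standardize_fit()]
#' @return transformed matrix
#' @export
standardize_apply <- function(X, tf) {
  sweep(sweep(X, 2, tf$center), 2, tf$scale, "/")
}

#' Train a soft-margin SVM under a kernel configuration
#'
#' Kernels: linear `x.y`; polynomial `(x.y + 1)^d`; RBF
#' `exp(-||x-y||^2 / (2 sigma^2))`. The regularization constant R maps to
#' the SVM cost parameter. Returns a model whose decision score is oriented
#' so that larger values mean apnea.
#'
#' @param X standardized feature matrix
#' @param y labels ("A"/"N"), at least 2 examples per class
#' @param cfg a [kernel_config()]
#' @param config pipeline configuration (polynomial offset)
#' @return a `svm_model` with `$predict_score(newX)` and
#'   `$predict_label(newX)`
#' @export
train_svm <- function(X, y, cfg, config = default_config()) {
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  yf <- factor(y, levels = c("A", "N"))
  args <- list(x = X, y = yf, scale = FALSE, cost = cfg$R, fitted = FALSE)
  args <- switch(cfg$kernel,
    linear = c(args, list(kernel = "linear")),
    poly = c(args, list(kernel = "polynomial", degree = cfg$d,
                        gamma = 1, coef0 = config$svm$poly_coef0)),
    rbf = c(args, list(kernel = "radial", gamma = 1 / (2 * cfg$sigma^2)))
  )
  fit <- do.call(e1071::svm, args)
  # libsvm orients the decision value toward the first training label
  flip <- if (fit$labels[1] == which(levels(yf) == "A")) 1 else -1
  predict_score <- function(newX) {
    pr <- stats::predict(fit, newX, decision.values = TRUE)
    flip * as.numeric(attr(pr, "decision.values"))
  }
  structure(
    list(fit = fit, config = cfg,
         predict_score = predict_score,
         predict_label = function(newX) {
           ifelse(predict_score(newX) > 0, "A", "N")
         }),
    class = "svm_model"
  )
}

#' Classification metrics from a confusion matrix
#'
#' Apnea is the positive class: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), accuracy = (TP+TN)/total, all in percent.
#'
#' @param tp,tn,fp,fn confusion counts
#' @return named vector `sensitivity`, `specificity`, `accuracy` (percent)
#' @export
metrics <- function(tp, tn, fp, fn) {
  if (tp + fn <= 0 || tn + fp <= 0) {
    stop("metrics need at least one example of each class")
  }
  c(sensitivity = tp / (tp + fn) * 100,
    specificity = tn / (tn + fp) * 100,
    accuracy = (tp + tn) / (tp + tn + fp + fn) * 100)
}

#' Area under the ROC curve, in percent
#'
#' Computed by the Mann-Whitney identity on score ranks (tied scores get
#' half credit), equivalent to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric decision scores (larger = more apneic)
#' @param labels "A"/"N" labels
#' @return AUC in `[0, 100]`
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "A"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0) * 100
}

make_stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", k, ")")
    }
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of one SVM configuration
#'
#' Per fold: the training portion is under-sampled to class balance,
#' z-scored with training statistics, and the SVM is trained; the untouched
#' test fold is scored with the training transform. Metrics are computed per
#' fold and from the pooled confusion.
#'
#' @param X feature matrix (rows = epochs)
#' @param y "A"/"N" labels
#' @param cfg a [kernel_config()]
#' @param k folds (default from config)
#' @param seed RNG seed controlling folds and under-sampling
#' @param config pipeline configuration
#' @param folds optional precomputed fold assignment (overrides `k`/`seed`
#'   for fold construction, e.g. to share folds across a grid)
#' @return a `cv_evaluation`: list with `config`, `folds` (per-fold metric
#'   data.frame), `mean`, `sd` (named vectors over sensitivity/specificity/
#'   accuracy/auc, percent), and `pooled` (metrics of the pooled confusion)
#' @export
kfold_cv <- function(X, y, cfg, k = NULL, seed = 1L,
                     config = default_config(), folds = NULL) {
  X <- as.matrix(X)
  k <- k %||% config$svm$k
  if (is.null(folds)) folds <- make_stratified_folds(y, k, seed)
  k <- max(folds)
  per_fold <- vector("list", k)
  conf <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    bal <- tr[undersample_idx(y[tr], seed + 1000L * f)]
    tfm <- standardize_fit(X[bal, , drop = FALSE])
    model <- train_svm(standardize_apply(X[bal, , drop = FALSE], tfm),
                       y[bal], cfg, config)
    sc <- model$predict_score(standardize_apply(X[te, , drop = FALSE], tfm))
    pred <- ifelse(sc > 0, "A", "N")
    tp <- sum(pred == "A" & y[te] == "A")
    tn <- sum(pred == "N" & y[te] == "N")
    fp <- sum(pred == "A" & y[te] == "N")
    fn <- sum(pred == "N" & y[te] == "A")
    conf <- conf + c(tp = tp, tn = tn, fp = fp, fn = fn)
    per_fold[[f]] <- c(fold = f, metrics(tp, tn, fp, fn),
                       auc = roc_auc(sc, y[te]))
  }
  fdf <- as.data.frame(do.call(rbind, per_fold))
  mcols <- c("sensitivity", "specificity", "accuracy", "auc")
  structure(
    list(config = cfg,
         folds = fdf,
         mean = colMeans(fdf[mcols]),
         sd = vapply(fdf[mcols], stats::sd, numeric(1)),
         pooled = metrics(conf["tp"], conf["tn"], conf["fp"], conf["fn"])),
    class = "cv_evaluation"
  )
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat("<cv_evaluation>", config_label(x$config), "-",
      nrow(x$folds), "folds\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  invisible(x)
}

#' Hill-climb over cumulative feature classes
#'
#' Evaluates the cumulative class sets A, AB, ABC, A-D, A-E against every
#' grid configuration with shared stratified folds, then keeps the set with
#' the greatest mean accuracy across configurations (ties broken by the
#' smaller accuracy standard deviation across configurations).
#'
#' @param feature_table feature table with `label` and feature columns
#' @param sr a `selection_result` (supplies `class_of`)
#' @param grid list of [kernel_config()]s (default [default_grid()])
#' @param k CV folds
#' @param seed RNG seed
#' @param config pipeline configuration
#' @return list with `table` (one row per class set x configuration),
#'   `per_set` (mean/sd accuracy per class set), `best_set` (e.g. "A"),
#'   `best_features` (its feature columns)
#' @export
hill_climb <- function(feature_table, sr, grid = NULL, k = NULL, seed = 1L,
                       config = default_config()) {
  grid <- grid %||% default_grid(config)
  k <- k %||% config$svm$k
  cls <- sr$class_of
  set_labels <- c("A", "AB", "ABC", "A-D", "A-E")
  sets <- list()
  acc_feats <- character(0)
  for (i in seq_len(5L)) {
    members <- names(cls)[cls == LETTERS[i]]
    acc_feats <- c(acc_feats, members)
    # an empty class adds nothing; skip its (duplicate) cumulative set
    if (length(members) > 0L) sets[[set_labels[i]]] <- acc_feats
  }
  if (length(sets) == 0L) stop("no selected features in any class")
  y <- feature_table$label
  folds <- make_stratified_folds(y, k, seed)
  rows <- list()
  for (set_name in names(sets)) {
    feats <- sets[[set_name]]
    X <- as.matrix(feature_table[, feats, drop = FALSE])
    X[!is.finite(X)] <- 0   # rare degenerate features: neutral after z-score
    for (cfg in grid) {
      cv <- kfold_cv(X, y, cfg, seed = seed, config = config, folds = folds)
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, kernel = cfg$kernel, R = cfg$R,
        d = cfg$d %||% NA, sigma = cfg$sigma %||% NA,
        sensitivity = cv$mean[["sensitivity"]],
        specificity = cv$mean[["specificity"]],
        accuracy = cv$mean[["accuracy"]],
        auc = cv$mean[["auc"]],
        sd_accuracy = cv$sd[["accuracy"]],
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  per_set <- do.call(rbind, lapply(split(tab, tab$set), function(d) {
    data.frame(set = d$set[1], mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy),
               stringsAsFactors = FALSE)
  }))
  per_set <- per_set[match(names(sets), per_set$set), ]
  best <- per_set$set[order(-per_set$mean_accuracy, per_set$sd_accuracy)][1]
  list(table = tab, per_set = per_set, best_set = best,
       best_features = sets[[best]])
}
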