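#' Unsupervised combined-similarity classifier
#'
#' The combined score of a drug pair is the arithmetic mean of its
#' standardized (z-scored) similarity features,
#' `s_comb = mean((x_j - mu_j) / sd_j)`; a pair is predicted to interact when
#' its combined score is strictly above a percentile threshold `t` (default:
#' the 90th percentile of the combined scores of the fitting rows, by the
#' nearest-rank definition). Standardization parameters are estimated on the
#' fitting set; features with zero standard deviation contribute 0 to every
#' score, so the model is invariant to affine rescaling of any input feature.
#' Class labels are never used for fitting — only for evaluation.
#'
#' @param features A data frame or matrix containing the feature columns
#'   (any of the 12 canonical columns present are used; a `label` column and
#'   id columns are ignored).
#' @param percentile Threshold percentile in (0, 100); default 90.
#' @param columns Feature columns to use; defaults to the intersection of
#'   [feature_names()] with the columns of `features`.
#' @return An object of class `combined_score`: list with `columns`, `mean`,
#'   `sd`, `percentile`, `threshold`.
#' @export
combined_score <- function(features, percentile = 90, columns = NULL) {
  if (!is_scalar_number(percentile) || percentile <= 0 || percentile >= 100) {
    stop("`percentile` must be in (0, 100)")
  }
  x <- feature_matrix(features, columns)
  if (nrow(x) < 2L) stop("need at least 2 rows to fit")
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  model <- structure(
    list(columns = colnames(x), mean = mu, sd = sd_,
         percentile = percentile, threshold = 0),
    class = "combined_score"
  )
  scores <- combined_scores(model, x)
  model$threshold <- nearest_rank_percentile(scores, percentile)
  model
}

# nearest-rank percentile: the ceiling(p/100 * n)-th smallest value
nearest_rank_percentile <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

feature_matrix <- function(features, columns = NULL) {
  features <- as.data.frame(features)
  columns <- columns %||% intersect(feature_names(), names(features))
  if (length(columns) == 0L) stop("no recognized feature columns")
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature columns absent: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(features[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values")
  x
}

combined_scores <- function(model, x) {
  z <- sweep(x, 2L, model$mean, "-")
  ok <- model$sd > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, model$sd[ok], "/")
  z[, !ok] <- 0
  rowMeans(z)
}

#' @export
print.combined_score <- function(x, ...) {
  cat(sprintf("<combined_score> %d features, threshold %.4f (percentile %g)\n",
              length(x$columns), x$threshold, x$percentile))
  invisible(x)
}

#' Predict with the combined-score classifier
#'
#' Scores are real-valued combined z-score means; the hard label is 1 iff
#' the score is strictly greater than the threshold. By default the
#' threshold fitted on the training rows is frozen; with
#' `refit_threshold = TRUE` the threshold percentile is recomputed on the
#' scored set itself (the within-sample variant).
#'
#' @param object A [combined_score()] model.
#' @param newdata Feature data with the fitted columns.
#' @param refit_threshold Recompute the percentile threshold on `newdata`'s
#'   own scores (default `FALSE`).
#' @param ... Unused.
#' @return A data frame with columns `score` and `label`, with attribute
#'   `threshold`.
#' @export
predict.combined_score <- function(object, newdata, refit_threshold = FALSE, ...) {
  x <- feature_matrix(newdata, object$columns)
  scores <- combined_scores(object, x)
  thr <- if (refit_threshold) nearest_rank_percentile(scores, object$percentile) else object$threshold
  structure(data.frame(score = scores, label = as.integer(scores > thr)),
            threshold = thr)
}

classifier_families <- c("tree", "knn", "svm_linear", "random_forest", "gbm")

default_grid <- function(family) {
  switch(family,
    tree = list(cp = c(0.001, 0.01, 0.05)),
    knn = list(k = seq(1L, 25L, by = 2L)),
    svm_linear = list(cost = c(0.01, 0.1, 1, 10)),
    random_forest = list(num.trees = 500L),
    gbm = list(nrounds = c(100L, 300L), max_depth = c(2L, 3L))
  )
}

grid_rows <- function(grid) {
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# fit one configuration on (x, y); returns an opaque fit object
fit_family <- function(family, x, y, params, seed) {
  switch(family,
    tree = rpart::rpart(y ~ ., data = data.frame(x, y = y), method = "class",
                        control = rpart::rpart.control(cp = params$cp)),
    knn = list(x = x, y = y, k = params$k),  # lazy learner: keep the data
    svm_linear = with_seed(seed,  # Platt scaling runs an internal CV
      e1071::svm(x, y, kernel = "linear", cost = params$cost,
                 probability = TRUE)),
    random_forest = ranger::ranger(
      x = x, y = y, num.trees = params$num.trees, probability = TRUE,
      importance = "impurity", seed = seed, num.threads = 1L),
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = params$max_depth,
                    eta = 0.1, subsample = 0.8, nthread = 1L,
                    seed = seed %% 2147483647),
      data = xgboost::xgb.DMatrix(x, label = as.integer(as.character(y)),
                                  nthread = 1L),
      nrounds = params$nrounds, verbose = 0)
  )
}

predict_family <- function(family, fit, x) {
  score <- switch(family,
    tree = stats::predict(fit, data.frame(x), type = "prob")[, "1"],
    knn = {
      pred <- class::knn(fit$x, x, fit$y, k = fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    svm_linear = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = stats::predict(fit, data = x, num.threads = 1L)$predictions[, "1"],
    gbm = stats::predict(fit, x)
  )
  unname(pmin(1, pmax(0, score)))
}

cv_accuracy <- function(family, x, y, params, folds, seed) {
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    fit <- fit_family(family, x[tr, , drop = FALSE], y[tr], params,
                      seed = stage_seed(seed, paste0("fold", f)))
    sc <- predict_family(family, fit, x[!tr, , drop = FALSE])
    mean(as.integer(sc >= 0.5) == as.integer(as.character(y[!tr])))
  }, numeric(1L))
  mean(acc)
}

#' Fit a supervised drug-pair classifier
#'
#' Trains one of five classifier families on a labelled feature matrix:
#' classification tree (`rpart`), k-nearest neighbours (Euclidean metric),
#' linear-kernel support vector machine, random forest (500 trees,
#' probability forest) or stochastic gradient boosting (shallow boosted
#' trees, learning rate 0.1). Hyperparameters (tree complexity, `k`, SVM
#' cost, boosting rounds/depth) are selected by internal `tune_folds`-fold
#' cross-validated accuracy on the training data only; the selected
#' configuration's accuracy is then estimated by `cv_folds`-fold
#' cross-validation and the model is refitted on the full training data.
#' Features are standardized (training mean/sd) for the distance- and
#' margin-based learners (kNN, SVM) and left raw for the tree-based ones.
#'
#' @param data A data frame with feature columns and a binary `label`
#'   column, e.g. the output of [featurize_topology()] +
#'   [featurize_semantic()].
#' @param family One of `"tree"`, `"knn"`, `"svm_linear"`,
#'   `"random_forest"`, `"gbm"`.
#' @param columns Feature columns (default: canonical columns present).
#' @param tune_folds Folds for hyperparameter selection (default 5).
#' @param cv_folds Folds for the accuracy estimate of the selected model
#'   (default 10; 0 skips the estimate).
#' @param grid Named list of hyperparameter vectors overriding the default
#'   grid.
#' @param seed Integer seed; fitting is deterministic given the seed.
#' @return An object of class `ddi_classifier`: list with `family`, `fit`,
#'   `params` (selected hyperparameters), `tuning` (grid results),
#'   `cv_accuracy`, `columns`, `center`/`scale` (for standardized families),
#'   `seed`.
#' @export
ddi_classifier <- function(data, family = classifier_families, columns = NULL,
                           tune_folds = 5L, cv_folds = 10L, grid = NULL,
                           seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), "label" %in% names(data))
  x <- feature_matrix(data, columns)
  y <- factor(as.integer(data$label), levels = c(0L, 1L))
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (nrow(x) < max(tune_folds, 2L)) stop("too few rows for cross-validation")
  standardized <- family %in% c("knn", "svm_linear")
  center <- scale_ <- NULL
  if (standardized) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2L, center, "-"), 2L, scale_, "/")
  }
  grid <- grid %||% default_grid(family)
  configs <- grid_rows(grid)
  tune_seed <- stage_seed(seed, "tune")
  tuning <- NULL
  if (length(configs) > 1L) {
    accs <- vapply(configs, function(p) cv_accuracy(family, x, y, p, tune_folds, tune_seed),
                   numeric(1L))
    tuning <- cbind(as.data.frame(do.call(rbind, lapply(configs, as.data.frame))),
                    accuracy = accs)
    best <- configs[[which.max(accs)]]
  } else {
    best <- configs[[1L]]
  }
  cvacc <- if (cv_folds >= 2L) {
    cv_accuracy(family, x, y, best, cv_folds, stage_seed(seed, "select"))
  } else NA_real_
  fit <- fit_family(family, x, y, best, seed = stage_seed(seed, "final"))
  structure(
    list(family = family, fit = fit, params = best, tuning = tuning,
         cv_accuracy = cvacc, columns = colnames(x),
         center = center, scale = scale_, seed = as.integer(seed)),
    class = "ddi_classifier"
  )
}

#' @export
print.ddi_classifier <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<ddi_classifier> family %s (%s)", x$family, p))
  if (!is.na(x$cv_accuracy)) cat(sprintf("; CV accuracy %.3f", x$cv_accuracy))
  cat("\n")
  invisible(x)
}

#' @export
summary.ddi_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$tuning)) {
    cat("hyperparameter search:\n")
    print(object$tuning, row.names = FALSE)
  }
  invisible(object)
}

#' Predict with a fitted drug-pair classifier
#'
#' @param object A [ddi_classifier()].
#' @param newdata Feature data with the training columns.
#' @param ... Unused.
#' @return A data frame with `score` (probability of the interacting class,
#'   in `[0, 1]`) and `label` (1 iff `score >= 0.5`).
#' @export
predict.ddi_classifier <- function(object, newdata, ...) {
  x <- feature_matrix(newdata, object$columns)
  if (!identical(colnames(x), object$columns)) stop("feature columns do not match training")
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2L, object$center, "-"), 2L, object$scale, "/")
  }
  score <- predict_family(object$family, object$fit, x)
  data.frame(score = score, label = as.integer(score >= 0.5))
}

#' Impurity-based feature importance of an ensemble classifier
#'
#' Available for the random-forest and gradient-boosting families, whose
#' tree ensembles yield a mean impurity-decrease (Gini gain) importance per
#' feature. Importances are reported on the absolute scale and min-max
#' normalized to 0-100 and 0-1 (the most important feature maps to 100/1,
#' the least important to 0).
#'
#' @param model A fitted [ddi_classifier()] of family `"random_forest"` or
#'   `"gbm"`.
#' @return An object of class `importance_report`: data frame with columns
#'   `feature`, `importance`, `rel_100`, `rel_1`, ordered as the training
#'   columns.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "ddi_classifier"))
  if (!model$family %in% c("random_forest", "gbm")) {
    stop("feature importance is available for random_forest and gbm only")
  }
  imp <- stats::setNames(numeric(length(model$columns)), model$columns)
  if (model$family == "random_forest") {
    raw <- ranger::importance(model$fit)
    imp[names(raw)] <- raw
  } else {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp[tab$Feature] <- tab$Gain
  }
  rng <- diff(range(imp))
  rel <- if (rng == 0) rep(0, length(imp)) else (imp - min(imp)) / rng
  structure(
    data.frame(feature = names(imp), importance = unname(imp),
               rel_100 = 100 * unname(rel), rel_1 = unname(rel),
               stringsAsFactors = FALSE),
    class = c("importance_report", "data.frame")
  )
}
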