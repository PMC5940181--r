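#' Confusion-matrix classification metrics
#'
#' Computes counts and derived rates for binary predictions. Ratios with a
#' zero denominator (e.g. precision under all-negative predictions) are
#' reported as `NA`, never silently as 0.
#'
#' @param truth,predicted Equal-length binary (0/1) label vectors.
#' @return An object of class `confusion_summary`: a one-row data frame with
#'   columns `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f1`, `tpr`,
#'   `fpr`, `tnr`, `fnr`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fn <- sum(truth == 1L & predicted == 0L)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- f1_score(precision, recall)
  structure(
    data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               tpr = recall, fpr = ratio(fp, fp + tn),
               tnr = ratio(tn, fp + tn), fnr = ratio(fn, tp + fn)),
    class = c("confusion_summary", "data.frame")
  )
}

#' Harmonic mean of precision and recall
#'
#' `NA` when either input is `NA` or both are zero.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return The F1 score(s).
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Threshold-free ranking metrics: AUROC and AUPR
#'
#' Builds the ROC and precision-recall curves over the distinct score
#' thresholds (tied scores grouped) and integrates both by the trapezoidal
#' rule. AUROC equals the probability that a random positive outscores a
#' random negative (ties counted half). AUPR is the trapezoidal area under
#' the precision-recall curve, anchored at recall 0 with the precision of
#' the top score group (not average precision).
#'
#' @param truth Binary (0/1) labels; both classes must be present.
#' @param scores Real-valued scores, larger = more likely positive.
#' @return An object of class `curve_summary`: list with `auroc`, `aupr`,
#'   `roc` (data frame `fpr`, `tpr`) and `pr` (data frame `recall`,
#'   `precision`).
#' @export
curve_metrics <- function(truth, scores) {
  if (length(truth) != length(scores)) stop("length mismatch")
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  n_pos <- sum(truth == 1L)
  n_neg <- sum(truth == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(1L - t)
  last <- which(grp != c(grp[-1L], -1L))  # last row of each score group
  tp <- tp[last]
  fp <- fp[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  rec0 <- c(0, rec)
  prec0 <- c(prec[1L], prec)
  aupr <- sum(diff(rec0) * (utils::head(prec0, -1L) + utils::tail(prec0, -1L)) / 2)
  structure(
    list(auroc = auroc, aupr = aupr,
         roc = data.frame(fpr = fpr, tpr = tpr),
         pr = data.frame(recall = rec0, precision = prec0)),
    class = "curve_summary"
  )
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("<curve_summary> AUROC %.4f, AUPR %.4f\n", x$auroc, x$aupr))
  invisible(x)
}

#' Friedman rank test over a datasets x methods performance matrix
#'
#' Each dataset (row) ranks the methods (columns), rank 1 for the best
#' (largest) value, average ranks on ties. The classic Friedman statistic
#' `chi2 = 12N/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` with `k - 1` degrees
#' of freedom is used, deliberately without the tie-correction factor; the
#' p-value comes from the chi-squared distribution.
#'
#' @param perf Numeric matrix (or data frame), datasets as rows, methods as
#'   columns, no missing cells.
#' @param larger_is_better Ranking direction (default `TRUE`).
#' @return An object of class `rank_comparison`: list with `ranks` (matrix),
#'   `mean_ranks`, `chi2`, `df`, `p_value`, `n_datasets`, `n_methods`.
#' @export
friedman_ranks <- function(perf, larger_is_better = TRUE) {
  perf <- as.matrix(perf)
  if (anyNA(perf)) stop("performance matrix contains missing cells")
  if (nrow(perf) < 2L || ncol(perf) < 2L) {
    stop("need at least 2 datasets and 2 methods")
  }
  sgn <- if (larger_is_better) -1 else 1
  ranks <- t(apply(sgn * perf, 1L, rank))
  dimnames(ranks) <- dimnames(perf)
  n <- nrow(perf)
  k <- ncol(perf)
  rbar <- colMeans(ranks)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  structure(
    list(ranks = ranks, mean_ranks = rbar, chi2 = chi2, df = k - 1L,
         p_value = stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE),
         n_datasets = n, n_methods = k),
    class = "rank_comparison"
  )
}

#' Nemenyi post-hoc comparison of mean ranks
#'
#' Pairwise p-values from the studentized-range distribution on mean-rank
#' differences: `q_ij = |Rbar_i - Rbar_j| / sqrt(k(k+1)/(12N))` compared to
#' the upper tail of `q / sqrt(2)` with `k` groups and infinite degrees of
#' freedom. The critical difference at level `alpha` is
#' `CD = q_alpha / sqrt(2) * sqrt(k(k+1)/(6N))`; method pairs whose mean
#' ranks differ by less than the CD are statistically indistinguishable.
#'
#' @param rc A [friedman_ranks()] result.
#' @param alpha Significance level for the critical difference (default 0.05).
#' @return `rc` with elements `p_matrix` (symmetric, unit diagonal),
#'   `critical_difference` and `alpha` added.
#' @export
nemenyi_posthoc <- function(rc, alpha = 0.05) {
  stopifnot(inherits(rc, "rank_comparison"))
  k <- rc$n_methods
  n <- rc$n_datasets
  if (k < 2L) stop("need at least 2 methods")
  se <- sqrt(k * (k + 1) / (12 * n))
  d <- abs(outer(rc$mean_ranks, rc$mean_ranks, "-"))
  p <- stats::ptukey(d / se * sqrt(2), nmeans = k, df = Inf, lower.tail = FALSE)
  diag(p) <- 1
  rc$p_matrix <- p
  rc$critical_difference <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2) *
    sqrt(k * (k + 1) / (6 * n))
  rc$alpha <- alpha
  rc
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("<rank_comparison> %d datasets x %d methods: chi2(%d) = %.4g, p = %.4g\n",
              x$n_datasets, x$n_methods, x$df, x$chi2, x$p_value))
  cat("mean ranks:\n")
  print(round(x$mean_ranks, 3))
  if (!is.null(x$critical_difference)) {
    cat(sprintf("critical difference (alpha %.2f): %.4g\n", x$alpha, x$critical_difference))
  }
  invisible(x)
}

#' Critical-difference diagram of a rank comparison
#'
#' Plots methods along their average rank with a bar spanning the critical
#' difference; methods within one CD of each other are joined.
#'
#' @param x A [nemenyi_posthoc()] result.
#' @param ... Passed to `plot`.
#' @export
plot.rank_comparison <- function(x, ...) {
  if (is.null(x$critical_difference)) x <- nemenyi_posthoc(x)
  r <- sort(x$mean_ranks)
  k <- length(r)
  graphics::plot(r, rep(0, k), ylim = c(-1.2, 0.6), xlim = range(r) + c(-0.5, 0.5),
                 yaxt = "n", ylab = "", xlab = "average rank", pch = 19, ...)
  graphics::text(r, 0.25, names(r), srt = 45, adj = 0, xpd = NA, cex = 0.9)
  graphics::segments(min(r), -0.6, min(r) + x$critical_difference, -0.6, lwd = 3)
  graphics::text(min(r) + x$critical_difference / 2, -0.8,
                 sprintf("CD = %.3g", x$critical_difference), cex = 0.8)
  # join groups not separated by the CD
  y <- -0.25
  i <- 1L
  while (i <= k) {
    j <- max(which(r - r[i] < x$critical_difference))
    if (j > i) {
      graphics::segments(r[i], y, r[j], y, lwd = 2)
      y <- y - 0.12
    }
    i <- i + 1L
  }
  invisible(x)
}

#' Compare average similarity of positive, negative and random drug pairs
#'
#' Each feature column is z-scaled over the pooled rows, the per-pair mean
#' of the scaled features is taken, and the three groups — positive-labelled
#' pairs, negative-labelled pairs, and freshly sampled random pairs from the
#' universal pair space — are compared with the Kruskal-Wallis rank-sum
#' test.
#'
#' @param features A `labeled_pairs` data frame carrying the feature columns
#'   and a `label` column.
#' @param net The `ddi_network` to sample random pairs from.
#' @param featurizer A function taking a `labeled_pairs` data frame of bare
#'   pairs and returning it with the same feature columns appended (the
#'   pipeline passes its topology+semantics featurizer).
#' @param n_random Number of random pairs (default: the positive count).
#' @param seed Integer seed for the random-pair draw.
#' @return An object of class `group_similarity`: list with `groups` (named
#'   list of per-pair average-similarity vectors), `means`, `statistic`,
#'   `p_value`.
#' @export
group_similarity_comparison <- function(features, net, featurizer,
                                        n_random = NULL, seed = 1L) {
  stopifnot(is.data.frame(features), "label" %in% names(features),
            inherits(net, "ddi_network"), is.function(featurizer))
  cols <- intersect(feature_names(), names(features))
  if (length(cols) == 0L) stop("no feature columns present")
  if (!any(features$label == 1L) || !any(features$label == 0L)) {
    stop("positive and negative labels must both be present")
  }
  n_random <- n_random %||% sum(features$label == 1L)
  if (n_random < 1L) stop("n_random must be at least 1")
  n <- n_nodes(net)
  rnd <- with_seed(stage_seed(seed, "random-pairs"), {
    k <- sample.int(universal_pair_count(net), n_random,
                    replace = n_random > universal_pair_count(net))
    ij <- pair_from_index(k, n)
    data.frame(drug1 = net$nodes[ij[, 1L]], drug2 = net$nodes[ij[, 2L]],
               label = NA_integer_, stringsAsFactors = FALSE)
  })
  class(rnd) <- c("labeled_pairs", "data.frame")
  rnd <- featurizer(rnd)
  pooled <- rbind(as.data.frame(features)[, cols, drop = FALSE],
                  as.data.frame(rnd)[, cols, drop = FALSE])
  z <- scale(as.matrix(pooled))
  z[, attr(z, "scaled:scale") == 0] <- 0
  avg <- rowMeans(z)
  grp <- c(ifelse(features$label == 1L, "positive", "negative"),
           rep("random", nrow(rnd)))
  kw <- stats::kruskal.test(avg, factor(grp))
  groups <- split(avg, grp)
  structure(
    list(groups = groups, means = vapply(groups, mean, numeric(1L)),
         statistic = unname(kw$statistic), p_value = kw$p.value),
    class = "group_similarity"
  )
}

#' @export
print.group_similarity <- function(x, ...) {
  cat("<group_similarity> mean scaled similarity by group:\n")
  print(round(x$means, 4))
  cat(sprintf("Kruskal-Wallis chi2 = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Hierarchical clustering of feature columns
#'
#' Features are z-scaled, treated as points in pair-space (one dimension per
#' row), and clustered agglomeratively with Ward's method on Euclidean
#' distances. Constant columns become all-zero vectors after scaling.
#'
#' @param features A data frame carrying at least two of the canonical
#'   feature columns.
#' @return An object of class `feature_dendrogram` (also `hclust`), plottable
#'   with `plot()`.
#' @export
feature_dendrogram <- function(features) {
  cols <- intersect(feature_names(), names(as.data.frame(features)))
  if (length(cols) < 2L) stop("need at least 2 feature columns")
  z <- scale(as.matrix(as.data.frame(features)[, cols, drop = FALSE]))
  z[, attr(z, "scaled:scale") == 0] <- 0
  h <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  class(h) <- c("feature_dendrogram", "hclust")
  h
}

#' Write a metrics report CSV
#'
#' One row per network x classifier x subset, with the standard column set:
#' precision, recall, F1, AUROC, AUPR plus the four classification rates.
#'
#' @param metrics A data frame with columns `network`, `classifier`,
#'   `subset`, `precision`, `recall`, `f1`, `auroc`, `aupr`, `fnr`, `fpr`,
#'   `tnr`, `tpr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  want <- c("network", "classifier", "subset", "precision", "recall", "f1",
            "auroc", "aupr", "fnr", "fpr", "tnr", "tpr")
  utils::write.csv(metrics[, intersect(want, names(metrics))], path, row.names = FALSE)
  invisible(path)
}
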