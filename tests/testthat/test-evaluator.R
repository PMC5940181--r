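test_that("confusion metrics cover the exact and degenerate cases", {
  perfect <- confusion_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fpr, 0)

  allneg <- confusion_metrics(c(1, 0, 1), c(0, 0, 0))
  expect_true(is.na(allneg$precision))
  expect_equal(allneg$recall, 0)

  m <- confusion_metrics(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0))
  expect_equal(m$tp + m$fp + m$tn + m$fn, 5)
  expect_equal(m$tnr, 1 - m$fpr)
  expect_equal(m$fnr, 1 - m$tpr)
  expect_error(confusion_metrics(c(1, 0), c(1, 0, 0)), "mismatch")
  expect_error(confusion_metrics(c(1, 2), c(1, 0)), "binary")
})

test_that("the published precision/recall pairs are F1-consistent", {
  # e.g. the unsupervised DrugBank row
  expect_equal(round(f1_score(0.63, 0.68), 2), 0.65)
  rep <- reported_metrics()
  expect_true(all(abs(f1_score(rep$precision, rep$recall) - rep$f1) <= 0.01))
})

test_that("curve metrics hit the boundary values and the null band", {
  perfect <- curve_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$aupr, 1)
  expect_error(curve_metrics(c(1, 1), c(0.3, 0.4)), "both classes")

  set.seed(8)
  truth <- rep(0:1, 1000)
  scores <- runif(2000)
  null <- curve_metrics(truth, scores)
  expect_gte(null$auroc, 0.45)
  expect_lte(null$auroc, 0.55)
})

test_that("AUROC equals normalized Mann-Whitney concordance counting", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(10:50, 1)
    truth <- rbinom(n, 1, 0.5)
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    u <- 0
    for (i in which(truth == 1)) {
      for (j in which(truth == 0)) {
        u <- u + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
    expect_equal(curve_metrics(truth, scores)$auroc,
                 u / (sum(truth == 1) * sum(truth == 0)), tolerance = 1e-12,
                 label = paste("seed", seed))
  }
})

test_that("friedman ranks follow the classic statistic without tie correction", {
  same <- matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  rc0 <- friedman_ranks(same)
  expect_equal(rc0$chi2, 0)
  expect_equal(rc0$p_value, 1)

  perf <- rbind(c(0.9, 0.5, 0.7), c(0.8, 0.6, 0.7), c(0.95, 0.6, 0.55))
  rc <- friedman_ranks(perf)
  expect_equal(unname(rc$ranks[1, ]), c(1, 3, 2))
  expect_equal(sum(rc$ranks[1, ]), 3 * 4 / 2)
  expect_equal(rc$df, 2)
  # hand-ranked rows: (1,3,2), (1,3,2), (1,2,3) -> mean ranks (1, 8/3, 7/3)
  rbar <- c(1, 8 / 3, 7 / 3)
  expect_equal(unname(rc$mean_ranks), rbar, tolerance = 1e-12)
  expect_equal(rc$chi2, 12 * 3 / (3 * 4) * sum((rbar - 2)^2), tolerance = 1e-12)
  expect_error(friedman_ranks(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("nemenyi post-hoc returns a symmetric unit-diagonal p-matrix", {
  same <- matrix(rep(c(0.6, 0.6, 0.6), 4), 4, 3, byrow = TRUE)
  rc <- nemenyi_posthoc(friedman_ranks(same))
  expect_true(all(rc$p_matrix == 1))

  perf <- reported_aupr_matrix("train")
  rc2 <- nemenyi_posthoc(friedman_ranks(perf))
  expect_equal(rc2$p_matrix, t(rc2$p_matrix))
  expect_equal(unname(diag(rc2$p_matrix)), rep(1, 5))
  # the random forest is ranked first on every network
  expect_equal(unname(rc2$mean_ranks["RF"]), 1)
  expect_gt(rc2$critical_difference, 0)
})

test_that("group similarity comparison separates planted from null signal", {
  ds <- generate_ddi_data(synth_config(n_drugs = 80, n_communities = 3,
                                       p_in = 0.35, p_out = 0.02, seed = 21))
  comm <- detect_communities(ds$network)
  featurizer <- function(p) {
    p <- featurize_topology(p, ds$network, comm)
    featurize_semantic(p, ds$atc, ds$mesh, ds$ade, ds$chem)
  }
  bp <- featurizer(balanced_pairs(ds$network, seed = 3))
  gs <- group_similarity_comparison(bp, ds$network, featurizer, seed = 5)
  expect_gt(gs$means[["positive"]], gs$means[["negative"]])
  expect_gt(gs$means[["positive"]], gs$means[["random"]])
  expect_lt(gs$p_value, 0.001)
})

test_that("group statistic matches explicit rank arithmetic on tiny inputs", {
  # 3 positives, 3 negatives, 3 random pairs with a single feature column, so
  # the scaled per-pair average is a monotone transform of that column and the
  # rank-sum oracle can be evaluated by hand on the raw values
  net <- ddi_network(t(combn(paste0("n", 1:6), 2)))  # K6: any pair is featurizable
  vals <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3)
  feats <- data.frame(drug1 = rep("n1", 6), drug2 = paste0("n", c(2:6, 2)),
                      label = rep(c(1L, 0L), each = 3), cn = vals)
  rnd_vals <- c(0.5, 0.45, 0.55)
  featurizer <- function(p) { p$cn <- rnd_vals[seq_len(nrow(p))]; p }
  gs <- group_similarity_comparison(feats, net, featurizer, n_random = 3, seed = 1)
  all_vals <- c(vals, rnd_vals)
  r <- rank(all_vals)
  g <- rep(c("positive", "negative", "random"), each = 3)
  n <- length(r)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  expect_equal(gs$statistic, h, tolerance = 1e-12)
  # identical groups give a vanishing statistic
  feats2 <- feats
  feats2$cn <- rep(c(0.3, 0.6, 0.9), 2)
  featurizer2 <- function(p) { p$cn <- c(0.3, 0.6, 0.9)[seq_len(nrow(p))]; p }
  gs2 <- group_similarity_comparison(feats2, net, featurizer2, n_random = 3, seed = 1)
  expect_equal(gs2$statistic, 0, tolerance = 1e-9)
  expect_equal(gs2$p_value, 1, tolerance = 1e-9)
})

test_that("feature dendrogram merges identical columns first at height zero", {
  set.seed(9)
  d <- data.frame(cn = rnorm(40), jc = rnorm(40), aai = rnorm(40))
  d$pa <- d$cn  # duplicate column up to scaling
  fd <- feature_dendrogram(d)
  expect_s3_class(fd, "hclust")
  expect_equal(sort(fd$labels[-fd$merge[1, ]]), c("cn", "pa"))
  expect_equal(fd$height[1], 0, tolerance = 1e-10)
  expect_true(all(diff(fd$height) >= -1e-10))
})

test_that("feature dendrogram separates topological from semantic blocks on planted data", {
  ds <- generate_ddi_data(synth_config(n_drugs = 150, n_communities = 3,
                                       p_in = 0.3, p_out = 0.02, seed = 31,
                                       missingness = c(atc = 0, mesh = 0, ade = 0, chem = 0)))
  comm <- detect_communities(ds$network)
  bp <- balanced_pairs(ds$network, seed = 6)
  f <- featurize_topology(bp, ds$network, comm)
  f <- featurize_semantic(f, ds$atc, ds$mesh, ds$ade, ds$chem)
  fd <- feature_dendrogram(f)
  cut <- stats::cutree(fd, k = 2)
  # the four semantic channels cluster away from the core topological block
  expect_equal(length(unique(cut[c("atc", "chem", "mesh", "ade")])), 1L)
  expect_equal(length(unique(cut[c("cn", "jc", "aai", "pa", "rai", "ccn", "cra")])), 1L)
  expect_false(cut[["atc"]] == cut[["cn"]])
})
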