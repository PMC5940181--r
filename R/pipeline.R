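#' Build a pipeline run configuration
#'
#' A run configuration names the input networks (edge-list files plus
#' optional attribute/fingerprint files, or synthetic-generator configs),
#' the featurization mode, split fractions, the unsupervised threshold
#' percentile, the classifier families and the seeds for an end-to-end run.
#'
#' Modes:
#' * `"within-sample"`: pair features are computed on the full network, and the
#'   unsupervised threshold is re-fitted on each scored subset. This is the
#'   within-sample protocol; its test rows are optimistic because test
#'   positives contribute their own edges to the topology.
#' * `"leakage-safe"`: the edges of test-positive pairs are removed from the
#'   graph before topological featurization and the training threshold is
#'   frozen for test scoring.
#'
#' @param networks A named list; each element is either a `synth_config`, a
#'   `synth_ddi`, a `ddi_network` (topology-only run) or a list with paths
#'   `edges` and optionally `atc`, `mesh`, `ade`, `chem`.
#' @param mode `"within-sample"` or `"leakage-safe"`.
#' @param train_frac Training fraction for the example split (default 0.66).
#' @param percentile Unsupervised threshold percentile (default 90).
#' @param classifiers Character vector of classifier families (default all
#'   five).
#' @param community_method Community detection method for the
#'   community-aware indices.
#' @param delta WIC stabilization constant.
#' @param max_positives Cap on positive pairs per network (`Inf` = all
#'   edges); balanced sampling keeps classes 1:1.
#' @param cv_folds,tune_folds Cross-validation folds passed to
#'   [ddi_classifier()].
#' @param n_random Random pairs for the group-similarity comparison
#'   (default: number of positives).
#' @param seed Root seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(networks, mode = c("within-sample", "leakage-safe"),
                       train_frac = 0.66, percentile = 90,
                       classifiers = classifier_families,
                       community_method = "modularity", delta = 0.001,
                       max_positives = Inf, cv_folds = 10L, tune_folds = 5L,
                       n_random = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.list(networks), length(networks) >= 1L)
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("network_", seq_along(networks))
  }
  bad <- setdiff(classifiers, classifier_families)
  if (length(bad) > 0L) stop("unknown classifier families: ", paste(bad, collapse = ", "))
  structure(
    list(networks = networks, mode = mode, train_frac = train_frac,
         percentile = percentile, classifiers = classifiers,
         community_method = community_method, delta = delta,
         max_positives = max_positives, cv_folds = cv_folds,
         tune_folds = tune_folds, n_random = n_random, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; each entry of
#' `networks` either holds file paths (`edges`, `atc`, `mesh`, `ade`,
#' `chem`) or a `synth` block of [synth_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  nets <- lapply(y$networks, function(nw) {
    if (!is.null(nw$synth)) do.call(synth_config, nw$synth) else nw
  })
  names(nets) <- names(y$networks)
  args <- y[setdiff(names(y), "networks")]
  do.call(run_config, c(list(networks = nets), args))
}

# resolve one network entry into list(network, atc, mesh, ade, chem)
resolve_network_input <- function(entry, name, seed) {
  if (inherits(entry, "synth_config")) {
    entry$seed <- stage_seed(seed, paste0(name, "/synth")) %% 2147483646L + 1L
    entry <- generate_ddi_data(entry)
  }
  if (inherits(entry, "synth_ddi")) {
    out <- list(network = entry$network, atc = entry$atc, mesh = entry$mesh,
                ade = entry$ade, chem = entry$chem)
    out$network$name <- name
    return(out)
  }
  if (inherits(entry, "ddi_network")) {
    return(list(network = entry, atc = NULL, mesh = NULL, ade = NULL, chem = NULL))
  }
  stopifnot(is.list(entry), !is.null(entry$edges))
  list(
    network = read_edge_list(entry$edges, name = name),
    atc = if (!is.null(entry$atc)) read_attribute_catalog(entry$atc, "ATC"),
    mesh = if (!is.null(entry$mesh)) read_attribute_catalog(entry$mesh, "MESH"),
    ade = if (!is.null(entry$ade)) read_attribute_catalog(entry$ade, "ADE"),
    chem = if (!is.null(entry$chem)) read_fingerprints(entry$chem)
  )
}

metrics_row <- function(network, classifier, subset, truth, pred, scores) {
  cm <- confusion_metrics(truth, pred)
  cv <- curve_metrics(truth, scores)
  cbind(data.frame(network = network, classifier = classifier, subset = subset,
                   stringsAsFactors = FALSE),
        cm[, c("precision", "recall", "f1")],
        data.frame(auroc = cv$auroc, aupr = cv$aupr),
        cm[, c("fnr", "fpr", "tnr", "tpr")])
}

#' Run the DDI link-prediction pipeline end to end
#'
#' For every configured network: load or generate the data, compute
#' descriptive statistics, detect communities, build a balanced labelled
#' pair set, split it 66/33 stratified, featurize both subsets (on the full
#' graph in `"within-sample"` mode, on the graph minus test-positive edges in
#' `"leakage-safe"` mode), fit the unsupervised combined-score classifier
#' and the configured supervised families, and evaluate all of them on both
#' subsets. Across networks, classifier test-AUPR values feed the Friedman +
#' Nemenyi rank comparison. The run is deterministic given the config seed.
#'
#' @param config A [run_config()].
#' @return An object of class `ddi_run_report`: list with `stats` (network
#'   statistics table), `metrics` (network x classifier x subset table),
#'   `aupr_matrix` (networks x methods, test subset), `rank_comparison`
#'   (`NULL` for a single network), `importance` (per network, per ensemble
#'   family), `group_similarity`, `dendrograms`, `features` (per-network
#'   train/test featurized pairs) and `config`.
#' @export
ddi_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stats_rows <- list()
  metric_rows <- list()
  importance <- list()
  group_sim <- list()
  dendros <- list()
  feats <- list()
  for (name in names(config$networks)) {
    inp <- resolve_network_input(config$networks[[name]], name, seed)
    net <- inp$network
    stats_rows[[name]] <- network_stats(net)
    comm_full <- detect_communities(net, method = config$community_method,
                                    seed = stage_seed(seed, paste0(name, "/comm")))

    n_pos <- min(n_edges(net), config$max_positives)
    positives <- if (n_pos < n_edges(net)) {
      net$edges[with_seed(stage_seed(seed, paste0(name, "/positives")),
                          sort(sample.int(n_edges(net), n_pos))), , drop = FALSE]
    } else net$edges
    pairs <- balanced_pairs(net, positives = positives,
                            seed = stage_seed(seed, paste0(name, "/pairs")))
    split <- partition_pairs(pairs, train_frac = config$train_frac,
                             seed = stage_seed(seed, paste0(name, "/split")))

    if (config$mode == "leakage-safe") {
      test_pos <- split$test[split$test$label == 1L, c("drug1", "drug2")]
      drop_keys <- pair_key(test_pos$drug1, test_pos$drug2)
      keep <- !(edge_keys(net) %in% drop_keys)
      feat_net <- ddi_network(net$edges[keep, , drop = FALSE], nodes = net$nodes,
                              name = net$name)
      feat_comm <- detect_communities(feat_net, method = config$community_method,
                                      seed = stage_seed(seed, paste0(name, "/comm")))
    } else {
      feat_net <- net
      feat_comm <- comm_full
    }
    featurizer <- function(p) {
      p <- featurize_topology(p, feat_net, feat_comm, delta = config$delta)
      featurize_semantic(p, atc = inp$atc, mesh = inp$mesh, ade = inp$ade,
                         chem = inp$chem)
    }
    train <- featurizer(split$train)
    test <- featurizer(split$test)
    feats[[name]] <- list(train = train, test = test)
    cols <- intersect(feature_names(), names(train))

    # unsupervised combined score
    cmb <- combined_score(train, percentile = config$percentile, columns = cols)
    refit <- config$mode == "within-sample"
    for (subset in c("train", "test")) {
      d <- if (subset == "train") train else test
      pr <- predict(cmb, d, refit_threshold = refit)
      metric_rows[[length(metric_rows) + 1L]] <-
        metrics_row(name, "unsupervised", subset, d$label, pr$label, pr$score)
    }

    # supervised families
    for (fam in config$classifiers) {
      model <- ddi_classifier(train, family = fam, columns = cols,
                              tune_folds = config$tune_folds,
                              cv_folds = config$cv_folds,
                              seed = stage_seed(seed, paste0(name, "/", fam)))
      for (subset in c("train", "test")) {
        d <- if (subset == "train") train else test
        pr <- predict(model, d)
        metric_rows[[length(metric_rows) + 1L]] <-
          metrics_row(name, fam, subset, d$label, pr$label, pr$score)
      }
      if (fam %in% c("random_forest", "gbm")) {
        importance[[name]][[fam]] <- feature_importance(model)
      }
    }

    both <- rbind(train, test)
    group_sim[[name]] <- group_similarity_comparison(
      both, net, featurizer,
      n_random = config$n_random,
      seed = stage_seed(seed, paste0(name, "/groups")))
    dendros[[name]] <- feature_dendrogram(both)
  }

  metrics <- do.call(rbind, metric_rows)
  test_m <- metrics[metrics$subset == "test", ]
  aupr <- stats::reshape(
    test_m[, c("network", "classifier", "aupr")],
    idvar = "network", timevar = "classifier", direction = "wide")
  rownames(aupr) <- aupr$network
  aupr <- as.matrix(aupr[, -1L, drop = FALSE])
  colnames(aupr) <- sub("^aupr\\.", "", colnames(aupr))
  rank_cmp <- if (nrow(aupr) >= 2L && ncol(aupr) >= 2L) {
    nemenyi_posthoc(friedman_ranks(aupr))
  } else NULL

  structure(
    list(stats = do.call(rbind, stats_rows), metrics = metrics,
         aupr_matrix = aupr, rank_comparison = rank_cmp,
         importance = importance, group_similarity = group_sim,
         dendrograms = dendros, features = feats, config = config),
    class = "ddi_run_report"
  )
}

#' @export
print.ddi_run_report <- function(x, ...) {
  cat("<ddi_run_report>\n\nNetwork statistics:\n")
  print(x$stats, row.names = FALSE, digits = 4)
  cat("\nEvaluation metrics:\n")
  num <- vapply(x$metrics, is.numeric, TRUE)
  m <- x$metrics
  m[num] <- lapply(m[num], round, 3)
  print(m, row.names = FALSE)
  if (!is.null(x$rank_comparison)) {
    cat("\n")
    print(x$rank_comparison)
  }
  invisible(x)
}

#' Write a run report's tables to a directory
#'
#' Emits `network_stats.csv`, `metrics.csv` (Tables-style rows with the
#' rate columns), `aupr_matrix.csv`, `rank_comparison.json` (mean ranks,
#' chi2, df, p, CD, pairwise p-matrix) and `importance_<network>_<family>.csv`
#' files, plus a `config.json` provenance echo.
#'
#' @param report A `ddi_run_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "ddi_run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network_stats(report$stats, file.path(dir, "network_stats.csv"))
  write_metrics_report(report$metrics, file.path(dir, "metrics.csv"))
  utils::write.csv(report$aupr_matrix, file.path(dir, "aupr_matrix.csv"))
  if (!is.null(report$rank_comparison)) {
    rc <- report$rank_comparison
    jsonlite::write_json(
      list(mean_ranks = as.list(rc$mean_ranks), chi2 = rc$chi2, df = rc$df,
           p_value = rc$p_value, critical_difference = rc$critical_difference,
           p_matrix = rc$p_matrix),
      file.path(dir, "rank_comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  for (nw in names(report$importance)) {
    for (fam in names(report$importance[[nw]])) {
      utils::write.csv(report$importance[[nw]][[fam]],
                       file.path(dir, sprintf("importance_%s_%s.csv", nw, fam)),
                       row.names = FALSE)
    }
  }
  cfg <- report$config
  cfg$networks <- lapply(cfg$networks, function(e) {
    if (inherits(e, "synth_config")) unclass(e) else if (is.list(e)) e else class(e)
  })
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
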