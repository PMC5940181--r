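#' Published benchmark tables for the five public DDI networks
#'
#' The package ships plain-text transcriptions of the published
#' link-prediction benchmark on five public DDI databases (DrugBank, KEGG,
#' NDF-RT, SemMedDB, Twosides): per-network/classifier/subset evaluation
#' metrics, network-level descriptive statistics, and pairwise edge-overlap
#' counts. These are *inputs* to the statistical-comparison machinery (rank
#' tests, convention checks) — reproducing them from raw data would require
#' the licensed source databases, which are outside this package's scope.
#'
#' @return `reported_metrics()`: a data frame with columns `network`,
#'   `classifier` (`unsupervised`, `DT`, `kNN`, `SVM`, `RF`, `GBM`),
#'   `subset` (`train`/`test`), `precision`, `recall`, `f1`, `auroc`,
#'   `aupr`. `reported_network_stats()` and `reported_overlaps()`: data
#'   frames mirroring the published summary tables.
#' @export
reported_metrics <- function() {
  utils::read.delim(system.file("extdata", "reported_metrics.tsv",
                                package = "ddilink"),
                    stringsAsFactors = FALSE)
}

#' @rdname reported_metrics
#' @export
reported_network_stats <- function() {
  utils::read.delim(system.file("extdata", "reported_network_stats.tsv",
                                package = "ddilink"),
                    stringsAsFactors = FALSE)
}

#' @rdname reported_metrics
#' @export
reported_overlaps <- function() {
  utils::read.delim(system.file("extdata", "reported_overlaps.tsv",
                                package = "ddilink"),
                    stringsAsFactors = FALSE)
}

#' Networks x classifiers AUPR matrix from the reported metrics
#'
#' Reshapes the supervised rows of [reported_metrics()] for one subset into
#' the 5 x 5 matrix consumed by [friedman_ranks()].
#'
#' @param subset `"train"` or `"test"`.
#' @return A numeric matrix, networks as rows, classifiers (`DT`, `kNN`,
#'   `SVM`, `RF`, `GBM`) as columns.
#' @export
reported_aupr_matrix <- function(subset = c("train", "test")) {
  subset <- match.arg(subset)
  m <- reported_metrics()
  m <- m[m$subset == subset & m$classifier != "unsupervised", ]
  classifiers <- c("DT", "kNN", "SVM", "RF", "GBM")
  networks <- unique(m$network)
  out <- matrix(NA_real_, length(networks), length(classifiers),
                dimnames = list(networks, classifiers))
  out[cbind(match(m$network, networks), match(m$classifier, classifiers))] <- m$aupr
  out
}
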