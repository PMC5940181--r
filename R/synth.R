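#' Configuration for the synthetic DDI data generator
#'
#' The generator emulates the statistical structure of curated DDI
#' networks — a giant component covering nearly all drugs, short paths, high
#' clustering, community structure and heavy-tailed degrees — together with
#' drug attribute channels whose similarity correlates with adjacency, so
#' that every pipeline stage can be exercised without the licensed source
#' databases.
#'
#' The network is drawn from a degree-corrected planted-partition model:
#' drugs are split into `n_communities` equal communities; a pair is linked
#' with probability `min(1, theta_i * theta_j * p)` where `p` is `p_in`
#' within a community and `p_out` between, and the propensities `theta` are
#' Pareto-distributed with tail exponent `degree_exponent` (mean-normalized;
#' `Inf` gives homogeneous degrees). Attribute codes mix a community-specific
#' pool and a global pool at rate `lambda` (the signal-strength knob: at
#' `lambda = 1` community pools are disjoint and attribute similarity is
#' maximally informative of adjacency; at `lambda = 0` attributes are
#' independent of the graph). Fingerprint bits copy a community prototype
#' with probability `lambda` and are otherwise independent Bernoulli draws.
#'
#' @param n_drugs Number of drugs (default 500).
#' @param n_communities Number of planted communities (default 5).
#' @param p_in,p_out Within-/between-community base edge probabilities
#'   (defaults 0.3 and 0.01).
#' @param degree_exponent Pareto tail exponent for degree propensities
#'   (default 2.5; `Inf` = homogeneous).
#' @param vocab_sizes Named integer vector: vocabulary size per channel.
#' @param codes_per_drug Named integer vector: annotations per drug per
#'   channel.
#' @param fp_bits Fingerprint length in bits (default 1024).
#' @param fp_density Expected fraction of set bits (default 0.1).
#' @param lambda Signal strength in `[0, 1]` (default 1).
#' @param missingness Named numeric vector: per-channel probability that a
#'   drug carries no record (default 0.05 each).
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 500L, n_communities = 5L,
                         p_in = 0.3, p_out = 0.01, degree_exponent = 2.5,
                         vocab_sizes = c(atc = 70L, mesh = 200L, ade = 260L),
                         codes_per_drug = c(atc = 4L, mesh = 10L, ade = 12L),
                         fp_bits = 1024L, fp_density = 0.1,
                         lambda = 1, missingness = c(atc = 0.05, mesh = 0.05,
                                                     ade = 0.05, chem = 0.05),
                         seed = 1L) {
  stopifnot(n_drugs >= 2L, n_communities >= 1L,
            p_out >= 0, p_in >= p_out, p_in <= 1,
            lambda >= 0, lambda <= 1,
            fp_bits >= 1L, fp_density > 0, fp_density < 1,
            all(missingness >= 0), all(missingness < 1),
            all(vocab_sizes > 0), all(codes_per_drug > 0))
  cfg <- list(n_drugs = as.integer(n_drugs), n_communities = as.integer(n_communities),
              p_in = p_in, p_out = p_out, degree_exponent = degree_exponent,
              vocab_sizes = vocab_sizes, codes_per_drug = codes_per_drug,
              fp_bits = as.integer(fp_bits), fp_density = fp_density,
              lambda = lambda, missingness = missingness, seed = as.integer(seed))
  exp_deg <- (n_drugs / n_communities - 1) * p_in +
    (n_drugs - n_drugs / n_communities) * p_out
  if (exp_deg < 1) warning("expected degree below 1; the network will be fragmented")
  class(cfg) <- "synth_config"
  cfg
}

# mean-normalized Pareto propensities; Inf exponent -> all ones
degree_propensities <- function(n, exponent) {
  if (!is.finite(exponent)) return(rep(1, n))
  u <- stats::runif(n)
  theta <- (1 - u)^(-1 / (exponent - 1))
  theta / mean(theta)
}

#' Generate a synthetic DDI dataset
#'
#' Draws the network, three attribute catalogs (ATC-, MeSH- and
#' side-effect-like) and the fingerprint catalog described by a
#' [synth_config()]. Fully deterministic given the config's seed.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_ddi`: list with `network`
#'   (`ddi_network`), `atc`, `mesh`, `ade` (`attribute_catalog`s), `chem`
#'   (`fingerprint_catalog`), `communities` (named integer ground-truth
#'   labels) and `config`.
#' @export
generate_ddi_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_drugs
  drugs <- sprintf("D%04d", seq_len(n))
  with_seed(config$seed, {
    comm <- sample(rep_len(seq_len(config$n_communities), n))
    names(comm) <- drugs
    theta <- degree_propensities(n, config$degree_exponent)

    # edges over all unordered pairs
    ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
    i <- ij[, "row"]; j <- ij[, "col"]
    p <- ifelse(comm[i] == comm[j], config$p_in, config$p_out)
    p <- pmin(1, theta[i] * theta[j] * p)
    sel <- stats::runif(length(p)) < p
    net <- ddi_network(cbind(drugs[i[sel]], drugs[j[sel]]), nodes = drugs,
                       name = "synthetic")

    # attribute channels: community pool vs global pool at rate lambda
    make_catalog <- function(channel) {
      v <- config$vocab_sizes[[channel]]
      k <- config$n_communities
      pool_size <- floor(v / (k + 1))
      pools <- lapply(seq_len(k), function(c) ((c - 1) * pool_size + 1):(c * pool_size))
      global <- (k * pool_size + 1):v
      m <- config$codes_per_drug[[channel]]
      keep <- stats::runif(n) >= config$missingness[[channel]]
      rows <- lapply(which(keep), function(d) {
        from_comm <- stats::runif(m) < config$lambda
        codes <- integer(m)
        pool <- pools[[comm[d]]]
        codes[from_comm] <- sample(pool, sum(from_comm), replace = m > length(pool))
        codes[!from_comm] <- sample(global, sum(!from_comm), replace = m > length(global))
        unique(codes)
      })
      df <- data.frame(
        drug_id = rep(drugs[keep], lengths(rows)),
        code = sprintf("%s%04d", toupper(channel), unlist(rows)),
        stringsAsFactors = FALSE
      )
      attribute_catalog(df, channel = toupper(channel))
    }
    atc <- make_catalog("atc")
    mesh <- make_catalog("mesh")
    ade <- make_catalog("ade")

    # fingerprints: community prototype bits at rate lambda
    proto <- matrix(stats::runif(config$n_communities * config$fp_bits) < config$fp_density,
                    nrow = config$n_communities)
    keep <- stats::runif(n) >= config$missingness[["chem"]]
    take_proto <- matrix(stats::runif(sum(keep) * config$fp_bits) < config$lambda,
                         nrow = sum(keep))
    noise <- matrix(stats::runif(sum(keep) * config$fp_bits) < config$fp_density,
                    nrow = sum(keep))
    bits <- ifelse(take_proto, proto[comm[keep], , drop = FALSE], noise)
    rownames(bits) <- drugs[keep]
    chem <- fingerprint_catalog(bits * 1L)

    structure(list(network = net, atc = atc, mesh = mesh, ade = ade,
                   chem = chem, communities = comm, config = config),
              class = "synth_ddi")
  })
}

#' @export
print.synth_ddi <- function(x, ...) {
  cat(sprintf("<synth_ddi> %d drugs, %d edges, %d communities (lambda %.2f, seed %d)\n",
              n_nodes(x$network), n_edges(x$network), x$config$n_communities,
              x$config$lambda, x$config$seed))
  invisible(x)
}

#' Summarize a synthetic dataset
#'
#' Network statistics (via [network_stats()]) plus per-channel coverage (the
#' fraction of drugs with a record).
#'
#' @param object A `synth_ddi` dataset.
#' @param ... Unused.
#' @return A list with `stats` (one-row data frame) and `coverage` (named
#'   numeric vector over atc/mesh/ade/chem).
#' @export
summary.synth_ddi <- function(object, ...) {
  n <- n_nodes(object$network)
  cov <- c(atc = length(object$atc$drugs), mesh = length(object$mesh$drugs),
           ade = length(object$ade$drugs), chem = length(object$chem$drugs)) / n
  list(stats = network_stats(object$network), coverage = cov)
}

#' Write a synthetic dataset to the pipeline's input formats
#'
#' Emits the edge-list TSV, the three long attribute TSVs, the fingerprint
#' TSV and a ground-truth JSON (community labels + config echo) into a
#' directory.
#'
#' @param dataset A `synth_ddi`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synth_data <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_ddi"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             atc = file.path(dir, "atc.tsv"),
             mesh = file.path(dir, "mesh.tsv"),
             ade = file.path(dir, "ade.tsv"),
             chem = file.path(dir, "fingerprints.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_edge_list(dataset$network, paths[["edges"]])
  for (ch in c("atc", "mesh", "ade")) {
    cat_ <- dataset[[ch]]
    df <- data.frame(drug_id = rep(cat_$drugs, lengths(cat_$sets)),
                     code = unlist(cat_$sets), stringsAsFactors = FALSE)
    utils::write.table(df, paths[[ch]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fp <- data.frame(drug_id = dataset$chem$drugs,
                   bits = apply(dataset$chem$bits, 1L, function(b) paste(as.integer(b), collapse = "")),
                   stringsAsFactors = FALSE)
  utils::write.table(fp, paths[["chem"]], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  jsonlite::write_json(
    list(communities = as.list(dataset$communities),
         config = cfg[setdiff(names(cfg), c("vocab_sizes", "codes_per_drug", "missingness"))]),
    paths[["truth"]], auto_unbox = TRUE)
  invisible(paths)
}
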