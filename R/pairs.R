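#' Size of the universal pair space
#'
#' The universal set `U` of possible links of a network with `|V|` nodes
#' contains `|V|(|V|-1)/2` unordered pairs; negatives for pair classification
#' are drawn from `U - E`.
#'
#' @param net A `ddi_network` with at least two nodes.
#' @return The number of unordered node pairs, as a double (may exceed the
#'   integer range).
#' @examples
#' universal_pair_count(ddi_network(rbind(c("a", "b"), c("b", "c"))))
#' @export
universal_pair_count <- function(net) {
  stopifnot(inherits(net, "ddi_network"))
  n <- n_nodes(net)
  if (n < 2L) stop("universal pair space requires at least 2 nodes")
  n * (n - 1) / 2
}

#' Randomly split a network's edges into training and test partitions
#'
#' Uniform partition without replacement: `floor(train_frac * |E|)` edges go
#' to the training partition, the remainder to the test partition. The two
#' partitions are disjoint and their union is `E`.
#'
#' @param net A `ddi_network` with at least 2 edges.
#' @param train_frac Fraction of edges for the training partition, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `edge_split`: list with `train` and `test`
#'   (two-column character matrices), `train_frac` and `seed`.
#' @export
split_edges <- function(net, train_frac = 0.66, seed = 1L) {
  stopifnot(inherits(net, "ddi_network"))
  if (!is_scalar_number(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)")
  }
  ne <- n_edges(net)
  if (ne < 2L) stop("need at least 2 edges to split")
  n_train <- floor(train_frac * ne)
  if (n_train < 1L || n_train >= ne) {
    stop("`train_frac` leaves an empty partition for ", ne, " edges")
  }
  idx <- with_seed(seed, sample.int(ne, n_train))
  structure(
    list(train = net$edges[sort(idx), , drop = FALSE],
         test = net$edges[sort(setdiff(seq_len(ne), idx)), , drop = FALSE],
         train_frac = train_frac, seed = as.integer(seed)),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("<edge_split> %d train / %d test edges (frac %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$train_frac, x$seed))
  invisible(x)
}

# Map pair index k in 1..n(n-1)/2 to (i, j), i < j, in enumeration order
# (1,2), (1,3), ..., (1,n), (2,3), ...
pair_from_index <- function(k, n) {
  k <- as.double(k)
  # i is the largest integer with (i-1)*(2n-i)/2 < k
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  base <- (i - 1) * n - i * (i - 1) / 2
  j <- k - base + i
  cbind(i, j)
}

#' Build a balanced labelled drug-pair set by negative sampling
#'
#' Positive examples are interacting pairs (by default every edge of the
#' network); negative examples are sampled uniformly without replacement from
#' the non-edge pair space `U - E` of the *full* network — never from `E`,
#' regardless of any train/test edge split, so sampled negatives can never be
#' hidden positives. Sampling is by rejection with a capped number of draws,
#' falling back to explicit enumeration of `U - E` on small graphs.
#'
#' @param net A `ddi_network`.
#' @param positives Two-column matrix of positive pairs; must be a subset of
#'   the network's edges. Defaults to all edges.
#' @param ratio Negatives per positive (1 = balanced, the default).
#' @param seed Integer seed.
#' @return An object of class `labeled_pairs`: a data frame with columns
#'   `drug1`, `drug2`, `label` (1 = interacting) and attributes `seed` and
#'   `sampling`.
#' @export
balanced_pairs <- function(net, positives = NULL, ratio = 1, seed = 1L) {
  stopifnot(inherits(net, "ddi_network"))
  if (is.null(positives)) positives <- net$edges
  if (is.data.frame(positives)) positives <- as.matrix(positives)
  positives <- canonical_pairs(as.character(positives[, 1L]), as.character(positives[, 2L]))
  ek <- edge_keys(net)
  pk <- paste(positives[, 1L], positives[, 2L], sep = "\r")
  if (!all(pk %in% ek)) stop("`positives` must be a subset of the network's edges")
  n_pos <- nrow(positives)
  if (n_pos < 1L) stop("no positive pairs supplied")
  n_neg <- round(ratio * n_pos)
  n <- n_nodes(net)
  n_univ <- universal_pair_count(net)
  avail <- n_univ - n_edges(net)
  if (n_neg > avail) {
    stop(sprintf("requested %d negatives but only %.0f non-edge pairs exist (deficit %.0f)",
                 n_neg, avail, n_neg - avail))
  }
  neg <- with_seed(stage_seed(seed, "negatives"), {
    chosen <- character(0L)
    rows <- NULL
    attempts <- 0L
    cap <- 50 * n_neg
    mode <- "rejection"
    while (length(chosen) < n_neg && attempts < cap && n_univ < 2^52) {
      need <- n_neg - length(chosen)
      k <- ceiling(runif(max(need * 2L, 16L)) * n_univ)
      attempts <- attempts + length(k)
      ij <- pair_from_index(k, n)
      cand <- cbind(net$nodes[ij[, 1L]], net$nodes[ij[, 2L]])
      key <- paste(cand[, 1L], cand[, 2L], sep = "\r")
      ok <- !(key %in% ek) & !(key %in% chosen) & !duplicated(key)
      take <- which(ok)[seq_len(min(need, sum(ok)))]
      chosen <- c(chosen, key[take])
      rows <- rbind(rows, cand[take, , drop = FALSE])
    }
    if (length(chosen) < n_neg) {
      # exact path: enumerate U - E (small graphs only)
      mode <- "enumeration"
      ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      allk <- paste(net$nodes[ij[, "row"]], net$nodes[ij[, "col"]], sep = "\r")
      pool <- which(!(allk %in% ek))
      take <- pool[sample.int(length(pool), n_neg)]
      rows <- cbind(net$nodes[ij[take, "row"]], net$nodes[ij[take, "col"]])
    }
    attr(rows, "mode") <- mode
    rows
  })
  out <- data.frame(
    drug1 = c(positives[, 1L], neg[, 1L]),
    drug2 = c(positives[, 2L], neg[, 2L]),
    label = rep(c(1L, 0L), c(n_pos, nrow(neg))),
    stringsAsFactors = FALSE
  )
  structure(out, seed = as.integer(seed), sampling = attr(neg, "mode"),
            class = c("labeled_pairs", "data.frame"))
}

#' Stratified train/test partition of labelled pairs
#'
#' Splits labelled examples into a training subset (`train_frac`, floor per
#' class) and a test subset (the remainder), preserving the class ratio to
#' within one example per class when `stratified = TRUE`. Subsets are
#' disjoint and their union is the input.
#'
#' @param pairs A `labeled_pairs` data frame (feature columns, if present,
#'   are carried along).
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify by class label (default `TRUE`).
#' @return A list with elements `train` and `test`, each a `labeled_pairs`
#'   data frame.
#' @export
partition_pairs <- function(pairs, train_frac = 0.66, seed = 1L, stratified = TRUE) {
  stopifnot(is.data.frame(pairs), "label" %in% names(pairs))
  if (!is_scalar_number(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("`train_frac` must be in (0, 1)")
  }
  lab <- pairs$label
  idx_train <- with_seed(stage_seed(seed, "partition"), {
    if (stratified) {
      if (any(table(lab) < 2L) || length(unique(lab)) < 2L) {
        stop("stratified partition needs at least 2 examples of each class")
      }
      unlist(lapply(unique(lab), function(cl) {
        rows <- which(lab == cl)
        rows[sample.int(length(rows), floor(train_frac * length(rows)))]
      }), use.names = FALSE)
    } else {
      sample.int(nrow(pairs), floor(train_frac * nrow(pairs)))
    }
  })
  idx_train <- sort(idx_train)
  keep_class <- function(d) {
    class(d) <- c("labeled_pairs", "data.frame")
    rownames(d) <- NULL
    d
  }
  list(train = keep_class(pairs[idx_train, , drop = FALSE]),
       test = keep_class(pairs[setdiff(seq_len(nrow(pairs)), idx_train), , drop = FALSE]))
}

#' Read or write labelled pair files
#'
#' TSV with header; columns `drug1`, `drug2`, `label`, plus any appended
#' feature columns.
#'
#' @param pairs A `labeled_pairs` data frame.
#' @param path File path.
#' @return `read_pairs` returns a `labeled_pairs` data frame; `write_pairs`
#'   returns `path` invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug1", "drug2", "label") %in% names(d)))
  structure(d, class = c("labeled_pairs", "data.frame"))
}
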