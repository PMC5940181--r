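#' Build an undirected simple drug-interaction network
#'
#' The DDI networks analysed by this package are undirected, unweighted simple
#' graphs: nodes are drug identifiers (opaque, case-sensitive strings) and an
#' edge records that the two drugs potentially interact. Construction
#' canonicalizes the edge set: reciprocal duplicates `(a,b)`/`(b,a)` collapse
#' to a single edge, exact duplicates are removed, and self-loops are dropped.
#' The numbers of dropped records are kept as attributes.
#'
#' @param edges A two-column matrix or data frame of drug identifiers, one row
#'   per interaction. May be empty.
#' @param nodes Optional character vector of node identifiers; nodes appearing
#'   in `edges` are always included, so this argument only adds isolated nodes.
#' @param name Label for the network.
#' @return An object of class `ddi_network` with elements `name`, `nodes`
#'   (sorted character vector) and `edges` (two-column character matrix in
#'   canonical order, lexicographically sorted).
#' @examples
#' net <- ddi_network(rbind(c("a", "b"), c("b", "a"), c("a", "a"), c("a", "c")))
#' n_edges(net) # 2
#' @export
ddi_network <- function(edges, nodes = NULL, name = "network") {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("`edges` must have two columns")
  a <- as.character(edges[, 1L])
  b <- as.character(edges[, 2L])
  loops <- a == b
  m <- canonical_pairs(a[!loops], b[!loops])
  key <- paste(m[, 1L], m[, 2L], sep = "\r")
  dup <- duplicated(key)
  m <- m[!dup, , drop = FALSE]
  ord <- order(m[, 1L], m[, 2L], method = "radix")
  m <- m[ord, , drop = FALSE]
  all_nodes <- sort(unique(c(as.character(nodes), m[, 1L], m[, 2L])), method = "radix")
  structure(
    list(name = as.character(name), nodes = all_nodes, edges = m),
    dropped_self_loops = sum(loops),
    dropped_duplicates = sum(dup),
    class = "ddi_network"
  )
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("<ddi_network> %s: %d nodes, %d edges\n", x$name, n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts of a network
#' @param net A `ddi_network`.
#' @return An integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

edge_keys <- function(net) paste(net$edges[, 1L], net$edges[, 2L], sep = "\r")

#' Convert a `ddi_network` to an igraph graph
#'
#' Isolated nodes are preserved as vertices.
#'
#' @param net A `ddi_network`.
#' @return An undirected `igraph` graph with vertex names equal to the drug ids.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ddi_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, t(matrix(match(net$edges, net$nodes), ncol = 2L)))
  }
  g
}

#' Read a drug-interaction edge list from a TSV file
#'
#' The format is plain text: two whitespace- or tab-separated drug identifiers
#' per line, `#`-prefixed comment lines allowed, no header. Direction is
#' ignored and the loaded graph is simplified (see [ddi_network()]).
#'
#' @param path Path to the edge-list file.
#' @param name Network label; defaults to the file name without extension.
#' @return A `ddi_network`.
#' @export
read_edge_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines[idx]), "[\t ]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d in %s: %s",
                 idx[bad[1L]], path, lines[idx[bad[1L]]]))
  }
  m <- t(vapply(toks, function(t) t[1:2], character(2L)))
  ddi_network(m, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a network's edge list to a TSV file
#'
#' Lines are canonicalized (lexicographically ordered within each pair) and
#' sorted, so writing then reading yields an identical edge set.
#'
#' @param net A `ddi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "ddi_network"))
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Average degree of an undirected graph
#'
#' The convention used throughout: `c = 2|E| / |V|`, i.e. the edge set is
#' treated as undirected regardless of how the source listed its records.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of edges.
#' @return The average degree.
#' @export
average_degree <- function(n_nodes, n_edges) 2 * n_edges / n_nodes

#' Descriptive statistics of a DDI network
#'
#' Computes the standard summary used to characterize interaction networks:
#' node and edge counts, average degree `c = 2|E|/|V|`, diameter `D` and
#' average shortest-path length `L` in hops on the giant component (unweighted
#' breadth-first distances, `L` averaged over connected ordered pairs),
#' average local clustering coefficient `C` (nodes of degree < 2 contribute
#' 0), and the giant-component fraction `GC`.
#'
#' @param net A `ddi_network`.
#' @return A one-row data frame with columns `network`, `n_nodes`, `n_edges`,
#'   `avg_degree`, `diameter`, `avg_path_length`, `clustering`,
#'   `giant_component`. For an edgeless network `diameter` and
#'   `avg_path_length` are `NA`.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "ddi_network"))
  if (n_nodes(net) < 1L) stop("network has no nodes")
  g <- as_igraph(net)
  nv <- n_nodes(net)
  ne <- n_edges(net)
  comp <- igraph::components(g)
  gc_size <- max(comp$csize)
  if (ne == 0L) {
    diam <- NA_real_
    apl <- NA_real_
    clus <- 0
  } else {
    giant <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    diam <- igraph::diameter(giant, unconnected = FALSE)
    apl <- igraph::mean_distance(giant, unconnected = FALSE)
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    clus <- mean(lc)
  }
  data.frame(
    network = net$name,
    n_nodes = nv,
    n_edges = ne,
    avg_degree = average_degree(nv, ne),
    diameter = diam,
    avg_path_length = apl,
    clustering = clus,
    giant_component = gc_size / nv,
    stringsAsFactors = FALSE
  )
}

#' Write a network statistics table to CSV
#'
#' @param stats A data frame as returned by [network_stats()] (one or more
#'   rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}

#' Overlap proportion between two edge sets
#'
#' Defined as the number of shared edges divided by the smaller of the two
#' edge counts; `NA` when either network has no edges.
#'
#' @param shared Number of edges present in both networks.
#' @param n_edges_1,n_edges_2 Edge counts of the two networks.
#' @return A proportion in `[0, 1]`, or `NA`.
#' @export
overlap_proportion <- function(shared, n_edges_1, n_edges_2) {
  m <- pmin(n_edges_1, n_edges_2)
  ifelse(m == 0, NA_real_, shared / m)
}

#' Pairwise edge overlaps between networks
#'
#' For every pair of networks, counts the edges (as unordered node pairs)
#' present in both, and expresses the count as a proportion of the smaller
#' edge set (see [overlap_proportion()]).
#'
#' @param nets A list of two or more `ddi_network` objects.
#' @return An object of class `ddi_overlap`: list with `edge_counts` (named
#'   vector), `shared` (symmetric count matrix) and `proportion` (symmetric
#'   proportion matrix, unit diagonal, `NA` rows for edgeless networks).
#' @export
network_overlap <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 2L,
            all(vapply(nets, inherits, TRUE, "ddi_network")))
  nms <- vapply(seq_along(nets), function(i) {
    nm <- nets[[i]]$name
    if (is.null(nm) || nm == "") paste0("network_", i) else nm
  }, character(1L))
  keys <- lapply(nets, edge_keys)
  k <- length(nets)
  shared <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    shared[i, i] <- length(keys[[i]])
    for (j in seq_len(k)) {
      if (j > i) {
        s <- length(intersect(keys[[i]], keys[[j]]))
        shared[i, j] <- s
        shared[j, i] <- s
      }
    }
  }
  counts <- diag(shared)
  prop <- shared
  for (i in seq_len(k)) for (j in seq_len(k)) {
    prop[i, j] <- if (i == j) {
      if (counts[i] == 0) NA_real_ else 1
    } else {
      overlap_proportion(shared[i, j], counts[i], counts[j])
    }
  }
  structure(list(edge_counts = counts, shared = shared, proportion = prop),
            class = "ddi_overlap")
}

#' @export
print.ddi_overlap <- function(x, digits = 2, ...) {
  k <- length(x$edge_counts)
  out <- matrix("", k, k, dimnames = dimnames(x$shared))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out[i, j] <- if (j >= i) {
      if (i == j) format(x$edge_counts[i]) else formatC(x$proportion[i, j], digits = digits, format = "f")
    } else {
      format(x$shared[i, j])
    }
  }
  cat("<ddi_overlap> diagonal: edge counts; lower: shared edges; upper: proportions\n")
  print(out, quote = FALSE)
  invisible(x)
}
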