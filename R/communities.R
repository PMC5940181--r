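#' Detect communities on a drug-interaction network
#'
#' The community-aware similarity indices (CCN, CRA, WIC) need a community
#' assignment. Two views are maintained:
#'
#' * the *partition* view assigns every node to exactly one community (as the
#'   WIC index requires), and
#' * the *overlapping* view assigns every node a set of communities (the set
#'   notation of CCN and CRA permits overlap).
#'
#' Methods:
#'
#' * `"modularity"` (default): greedy modularity maximization
#'   (`igraph::cluster_fast_greedy`), a deterministic partition; the
#'   overlapping view is then the singleton set of each node's community.
#' * `"kclique"`: 3-clique percolation — communities are unions of maximal
#'   cliques of size >= 3 chained by shared (k-1)-node overlaps; nodes may
#'   belong to several communities and nodes in no 3-clique form singletons.
#'   The partition view takes each node's first community. Intended for small
#'   graphs (clique enumeration).
#'
#' Isolated nodes always form singleton communities.
#'
#' @param net A `ddi_network`.
#' @param method `"modularity"` or `"kclique"`.
#' @param seed Integer seed (recorded; both methods are deterministic).
#' @param k Clique size for `"kclique"` (default 3).
#' @return An object of class `community_assignment`: list with `partition`
#'   (named integer vector), `overlapping` (named list of integer vectors),
#'   `method`, `k`, `seed`, `n_communities`.
#' @export
detect_communities <- function(net, method = c("modularity", "kclique"),
                               seed = 1L, k = 3L) {
  stopifnot(inherits(net, "ddi_network"))
  method <- match.arg(method)
  if (n_nodes(net) < 1L) stop("network has no nodes")
  g <- as_igraph(net)
  if (method == "modularity") {
    part <- with_seed(seed, {
      if (n_edges(net) == 0L) {
        seq_len(n_nodes(net))
      } else {
        igraph::membership(igraph::cluster_fast_greedy(g))
      }
    })
    part <- as.integer(part)
    names(part) <- net$nodes
    overlapping <- lapply(part, function(p) p)
  } else {
    overlapping <- kclique_communities(g, k = k)
    names(overlapping) <- net$nodes
    part <- vapply(overlapping, function(s) s[1L], integer(1L))
  }
  structure(
    list(partition = part, overlapping = overlapping, method = method,
         k = as.integer(k), seed = as.integer(seed),
         n_communities = length(unique(unlist(overlapping)))),
    class = "community_assignment"
  )
}

# 3-clique (k-clique) percolation on an igraph graph. Returns a list mapping
# each vertex (in graph order) to an integer vector of community ids; vertices
# in no k-clique get a fresh singleton id.
kclique_communities <- function(g, k = 3L) {
  nv <- igraph::vcount(g)
  cl <- igraph::max_cliques(g, min = k)
  comm_of <- vector("list", nv)
  if (length(cl) > 0L) {
    cl <- lapply(cl, function(x) sort(as.integer(x)))
    # union-find over cliques: adjacent iff they share >= k-1 vertices
    parent <- seq_along(cl)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (length(cl) > 1L) {
      for (i in seq_along(cl)) {
        for (j in seq_len(i - 1L)) {
          if (length(intersect(cl[[i]], cl[[j]])) >= k - 1L) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
    roots <- vapply(seq_along(cl), find, 1L)
    comm_id <- match(roots, unique(roots))
    for (i in seq_along(cl)) {
      for (v in cl[[i]]) comm_of[[v]] <- union(comm_of[[v]], comm_id[i])
    }
  }
  next_id <- if (length(cl) > 0L) max(unlist(comm_of)) else 0L
  for (v in seq_len(nv)) {
    if (is.null(comm_of[[v]])) {
      next_id <- next_id + 1L
      comm_of[[v]] <- next_id
    } else {
      comm_of[[v]] <- sort(comm_of[[v]])
    }
  }
  comm_of
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("<community_assignment> method %s: %d communities over %d nodes\n",
              x$method, x$n_communities, length(x$partition)))
  invisible(x)
}
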