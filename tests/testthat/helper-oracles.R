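# Independent brute-force oracles used across the suite. These deliberately
# work from the raw edge list with plain loops and set arithmetic, sharing no
# code with the package implementation they check.

# Erdos-Renyi graph as a ddi_network; nodes n01..nNN so ordering is stable.
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sel <- runif(nrow(ij)) < p
  ddi_network(cbind(nodes[ij[sel, 1]], nodes[ij[sel, 2]]), nodes = nodes,
              name = sprintf("er_%d_%d", n, seed))
}

# adjacency list (named list of character vectors) straight from the edges
bf_adjacency <- function(net) {
  adj <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (v in net$nodes) adj[[v]] <- character(0)
  if (nrow(net$edges) > 0) {
    for (r in seq_len(nrow(net$edges))) {
      a <- net$edges[r, 1]; b <- net$edges[r, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# single-source BFS hop counts; unreachable nodes get Inf
bf_bfs <- function(adj, src) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# all seven descriptive statistics by exhaustive enumeration
bf_stats <- function(net) {
  adj <- bf_adjacency(net)
  n <- length(adj)
  deg <- sapply(adj, length)
  # components via repeated BFS
  comp <- setNames(rep(NA_integer_, n), names(adj))
  cid <- 0
  for (v in names(adj)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[names(which(is.finite(bf_bfs(adj, v))))] <- cid
    }
  }
  sizes <- table(comp)
  giant <- names(comp)[comp == as.integer(names(sizes)[which.max(sizes)])]
  # local clustering: fraction of neighbour pairs that are linked; deg<2 -> 0
  lc <- sapply(names(adj), function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    links <- 0
    for (i in seq_along(nb)) for (j in seq_along(nb)) {
      if (j > i && nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    links / choose(length(nb), 2)
  })
  dists <- c()
  if (length(giant) > 1) {
    for (v in giant) {
      d <- bf_bfs(adj, v)[setdiff(giant, v)]
      dists <- c(dists, d)
    }
  }
  list(
    n_nodes = n, n_edges = nrow(net$edges), avg_degree = 2 * nrow(net$edges) / n,
    diameter = if (length(dists)) max(dists) else NA_real_,
    avg_path_length = if (length(dists)) mean(dists) else NA_real_,
    clustering = mean(lc), giant_component = max(sizes) / n
  )
}

# all eight topological indices by direct set arithmetic on the edge list;
# comm_sets: named list of community-id vectors, part: named partition vector
bf_topo <- function(net, x, y, comm_sets, part, delta = 0.001) {
  adj <- bf_adjacency(net)
  gx <- adj[[x]]; gy <- adj[[y]]
  common <- intersect(gx, gy)
  deg <- sapply(adj, length)
  cxy <- intersect(comm_sets[[x]], comm_sets[[y]])
  bonus <- sapply(common, function(z) length(intersect(comm_sets[[z]], cxy)))
  if (length(common) == 0) bonus <- numeric(0)
  w <- if (length(common) > 0 && part[[x]] == part[[y]]) {
    sum(vapply(common, function(z) part[[z]] == part[[x]], logical(1)))
  } else 0
  ic <- length(common) - w
  c(cn = length(common),
    jc = if (length(union(gx, gy)) == 0) 0 else length(common) / length(union(gx, gy)),
    aai = if (length(common) == 0) 0 else sum(1 / log(deg[common])),
    pa = length(gx) * length(gy),
    rai = if (length(common) == 0) 0 else sum(1 / deg[common]),
    ccn = length(common) + sum(bonus),
    cra = if (length(common) == 0) 0 else sum((1 + bonus) / deg[common]),
    wic = if (length(common) == 0) 0 else w / (ic + delta))
}

# random overlapping community structure over a network's nodes
rand_communities <- function(net, n_comm = 4, seed = 1) {
  set.seed(seed)
  ov <- lapply(net$nodes, function(v) {
    sort(sample.int(n_comm, sample.int(min(3, n_comm), 1)))
  })
  names(ov) <- net$nodes
  part <- vapply(ov, function(s) s[1], integer(1))
  structure(list(partition = part, overlapping = ov, method = "manual",
                 k = NA_integer_, seed = seed, n_communities = n_comm),
            class = "community_assignment")
}

# the five-pointed kite used in the worked examples:
# edges a-c, b-c, a-d, b-d, c-d
example_graph <- function() {
  ddi_network(rbind(c("a", "c"), c("b", "c"), c("a", "d"), c("b", "d"), c("c", "d")))
}

single_community <- function(net) {
  part <- setNames(rep(1L, length(net$nodes)), net$nodes)
  structure(list(partition = part,
                 overlapping = lapply(part, function(p) p),
                 method = "manual", k = NA_integer_, seed = 0L, n_communities = 1L),
            class = "community_assignment")
}

# small labelled feature set with a planted signal for predictor tests
blob_data <- function(n = 200, shift = 3, seed = 1, p = 4) {
  set.seed(seed)
  lab <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p) + shift * lab
  d <- as.data.frame(x)
  names(d) <- feature_names()[seq_len(p)]
  d$label <- lab
  d
}
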