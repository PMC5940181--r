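#' Neighborhood index of a network
#'
#' Precomputes, for every node `x`, the neighbour set `Gamma(x)` and the
#' degree `d(x) = |Gamma(x)|`; all topological indices are defined in terms
#' of these sets.
#'
#' @param net A `ddi_network`.
#' @return An object of class `neighbor_index`: list with `neighbors` (named
#'   list of integer vectors, node ids as indices into `nodes`), `degree`
#'   (named integer vector) and `nodes`.
#' @export
neighbor_index <- function(net) {
  stopifnot(inherits(net, "ddi_network"))
  nodes <- net$nodes
  n <- length(nodes)
  i1 <- match(net$edges[, 1L], nodes)
  i2 <- match(net$edges[, 2L], nodes)
  nb <- split(c(i2, i1), factor(c(i1, i2), levels = seq_len(n)))
  nb <- lapply(nb, function(v) sort(unique(v)))
  names(nb) <- nodes
  deg <- vapply(nb, length, 1L)
  structure(list(neighbors = nb, degree = deg, nodes = nodes),
            class = "neighbor_index")
}

node_pos <- function(idx, x) {
  p <- match(x, idx$nodes)
  if (is.na(p)) stop("unknown node: ", x)
  p
}

#' Classical topological similarity indices
#'
#' The five community-agnostic link-prediction indices for a node pair
#' `(x, y)` with common-neighbour set `L = Gamma(x) n Gamma(y)`:
#'
#' * `cn`: `|L|` — common neighbours;
#' * `jc`: `|L| / |Gamma(x) u Gamma(y)|` — Jaccard coefficient (0 when the
#'   union is empty);
#' * `aai`: `sum over z in L of 1/ln|Gamma(z)|` — Adamic-Adar index (natural
#'   logarithm; a common neighbour in a simple graph always has degree >= 2);
#' * `pa`: `|Gamma(x)| * |Gamma(y)|` — preferential attachment;
#' * `rai`: `sum over z in L of 1/|Gamma(z)|` — resource allocation.
#'
#' @param kind One of `"cn"`, `"jc"`, `"aai"`, `"pa"`, `"rai"`.
#' @param x,y Distinct node identifiers present in the index.
#' @param idx A [neighbor_index()].
#' @return A single numeric score.
#' @examples
#' net <- ddi_network(rbind(c("a","c"), c("b","c"), c("a","d"), c("b","d"), c("c","d")))
#' idx <- neighbor_index(net)
#' classical_index("cn", "a", "b", idx)  # 2
#' classical_index("jc", "a", "b", idx)  # 1
#' @export
classical_index <- function(kind = c("cn", "jc", "aai", "pa", "rai"), x, y, idx) {
  kind <- match.arg(kind)
  stopifnot(inherits(idx, "neighbor_index"))
  if (identical(as.character(x), as.character(y))) stop("x and y must differ")
  px <- node_pos(idx, x)
  py <- node_pos(idx, y)
  gx <- idx$neighbors[[px]]
  gy <- idx$neighbors[[py]]
  common <- intersect(gx, gy)
  switch(kind,
    cn = length(common),
    jc = {
      u <- length(gx) + length(gy) - length(common)
      if (u == 0L) 0 else length(common) / u
    },
    aai = if (length(common) == 0L) 0 else sum(1 / log(idx$degree[common])),
    pa = length(gx) * length(gy),
    rai = if (length(common) == 0L) 0 else sum(1 / idx$degree[common])
  )
}

#' Community-aware topological similarity indices
#'
#' The three indices that combine the common-neighbour set
#' `L = Gamma(x) n Gamma(y)` with a community assignment (`C(n)` is the set
#' of communities of node `n` in the overlapping view):
#'
#' * `ccn`: `|L| + sum over i in L of |C(i) n C(x) n C(y)|` — common
#'   neighbours with an extra point for every community shared by `x`, `y`
#'   and the neighbour;
#' * `cra`: `sum over i in L of (1 + |C(i) n C(x) n C(y)|) / d(i)` —
#'   resource allocation with the same community bonus;
#' * `wic`: `|L_W| / (|L_IC| + delta)` where, in the partition view, `L_W`
#'   are common neighbours in the same community as *both* `x` and `y` and
#'   `L_IC` the remaining common neighbours; `delta > 0` guards the division
#'   when all common neighbours are within-community. When `x` and `y` lie
#'   in different communities `L_W` is empty and `wic = 0`.
#'
#' @param kind One of `"ccn"`, `"cra"`, `"wic"`.
#' @param x,y Distinct node identifiers present in the index.
#' @param idx A [neighbor_index()].
#' @param comm A [detect_communities()] assignment covering both nodes and
#'   all common neighbours.
#' @param delta Small positive constant for `wic` (default 0.001).
#' @return A single numeric score.
#' @export
community_index <- function(kind = c("ccn", "cra", "wic"), x, y, idx, comm,
                            delta = 0.001) {
  kind <- match.arg(kind)
  stopifnot(inherits(idx, "neighbor_index"), inherits(comm, "community_assignment"))
  if (delta <= 0) stop("`delta` must be positive")
  if (identical(as.character(x), as.character(y))) stop("x and y must differ")
  px <- node_pos(idx, x)
  py <- node_pos(idx, y)
  common <- intersect(idx$neighbors[[px]], idx$neighbors[[py]])
  nodes <- idx$nodes
  if (kind == "wic") {
    part <- comm$partition
    cx <- part[[nodes[px]]]
    cy <- part[[nodes[py]]]
    if (length(common) == 0L) return(0)
    same <- cx == cy & part[nodes[common]] == cx
    n_w <- sum(same)
    n_ic <- length(common) - n_w
    return(n_w / (n_ic + delta))
  }
  ov <- comm$overlapping
  cxy <- intersect(ov[[nodes[px]]], ov[[nodes[py]]])
  bonus <- vapply(common, function(i) length(intersect(ov[[nodes[i]]], cxy)), 1L)
  if (kind == "ccn") {
    length(common) + sum(bonus)
  } else {
    if (length(common) == 0L) 0 else sum((1 + bonus) / idx$degree[common])
  }
}

topo_feature_names <- c("cn", "jc", "aai", "pa", "rai", "ccn", "cra", "wic")
semantic_feature_names <- c("atc", "chem", "mesh", "ade")

#' Names of the 12 pair-feature columns, in canonical order
#'
#' Eight topological indices followed by four semantic similarities.
#'
#' @return A character vector of length 12.
#' @export
feature_names <- function() c(topo_feature_names, semantic_feature_names)

# all eight indices for one pair, given integer node positions
pair_topology <- function(px, py, idx, comm, delta) {
  gx <- idx$neighbors[[px]]
  gy <- idx$neighbors[[py]]
  dx <- length(gx)
  dy <- length(gy)
  common <- intersect(gx, gy)
  ncn <- length(common)
  u <- dx + dy - ncn
  degc <- idx$degree[common]
  nodes <- idx$nodes
  ov <- comm$overlapping
  cxy <- intersect(ov[[nodes[px]]], ov[[nodes[py]]])
  bonus <- if (ncn == 0L) integer(0L) else
    vapply(common, function(i) length(intersect(ov[[nodes[i]]], cxy)), 1L)
  part <- comm$partition
  cx <- part[[nodes[px]]]
  n_w <- if (ncn == 0L || cx != part[[nodes[py]]]) 0L else sum(part[nodes[common]] == cx)
  c(cn = ncn,
    jc = if (u == 0L) 0 else ncn / u,
    aai = if (ncn == 0L) 0 else sum(1 / log(degc)),
    pa = dx * dy,
    rai = if (ncn == 0L) 0 else sum(1 / degc),
    ccn = ncn + sum(bonus),
    cra = if (ncn == 0L) 0 else sum((1 + bonus) / degc),
    wic = if (ncn == 0L) 0 else n_w / ((ncn - n_w) + delta))
}

#' Append the eight topological feature columns to a labelled pair set
#'
#' Computes all eight indices for every pair on the supplied graph. Which
#' graph to featurize on (the full network, or a training graph with test
#' edges removed) is the caller's choice — see the vignette on information
#' leakage.
#'
#' @param pairs A `labeled_pairs` data frame.
#' @param net The `ddi_network` to compute topology on; every pair endpoint
#'   must be one of its nodes (an absent endpoint is an error, not a silent
#'   zero).
#' @param comm A [detect_communities()] assignment on `net`; computed with
#'   the default method if missing.
#' @param delta WIC stabilization constant (default 0.001).
#' @return `pairs` with columns `cn`, `jc`, `aai`, `pa`, `rai`, `ccn`,
#'   `cra`, `wic` appended.
#' @export
featurize_topology <- function(pairs, net, comm = NULL, delta = 0.001) {
  stopifnot(is.data.frame(pairs), inherits(net, "ddi_network"))
  if (delta <= 0) stop("`delta` must be positive")
  if (is.null(comm)) comm <- detect_communities(net)
  idx <- neighbor_index(net)
  p1 <- match(pairs$drug1, idx$nodes)
  p2 <- match(pairs$drug2, idx$nodes)
  bad <- which(is.na(p1) | is.na(p2))
  if (length(bad) > 0L) {
    stop("pair endpoints absent from network: ",
         paste(utils::head(paste(pairs$drug1[bad], pairs$drug2[bad], sep = "-"), 5L),
               collapse = ", "))
  }
  feats <- t(vapply(seq_len(nrow(pairs)),
                    function(r) pair_topology(p1[r], p2[r], idx, comm, delta),
                    numeric(8L)))
  colnames(feats) <- topo_feature_names
  out <- cbind(pairs, as.data.frame(feats))
  class(out) <- class(pairs)
  out
}
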