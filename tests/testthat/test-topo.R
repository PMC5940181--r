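test_that("classical indices reproduce the worked example", {
  net <- example_graph()  # a-c, b-c, a-d, b-d, c-d
  idx <- neighbor_index(net)
  expect_equal(classical_index("cn", "a", "b", idx), 2)
  expect_equal(classical_index("jc", "a", "b", idx), 1)
  expect_equal(classical_index("pa", "a", "b", idx), 4)
  expect_equal(classical_index("rai", "a", "b", idx), 2 / 3, tolerance = 1e-12)
  expect_equal(classical_index("aai", "a", "b", idx), 2 / log(3), tolerance = 1e-12)
})

test_that("identical and disjoint neighbourhoods hit the boundary values", {
  net <- example_graph()
  idx <- neighbor_index(net)
  expect_equal(classical_index("jc", "a", "b", idx), 1)  # Gamma(a) == Gamma(b)
  iso <- ddi_network(rbind(c("a", "b"), c("c", "d")))
  idx2 <- neighbor_index(iso)
  for (k in c("cn", "jc", "aai", "rai")) {
    expect_equal(classical_index(k, "a", "c", idx2), 0)
  }
  expect_equal(classical_index("pa", "a", "c", idx2), 1)
  expect_error(classical_index("cn", "a", "a", idx2), "differ")
  expect_error(classical_index("cn", "a", "zz", idx2), "unknown node")
})

test_that("community indices reproduce the worked example", {
  net <- example_graph()
  idx <- neighbor_index(net)
  one <- single_community(net)
  expect_equal(community_index("ccn", "a", "b", idx, one), 4)         # 2 + 2
  expect_equal(community_index("cra", "a", "b", idx, one), 4 / 3, tolerance = 1e-12)
  expect_equal(community_index("wic", "a", "b", idx, one, delta = 0.001), 2000)
  expect_error(community_index("wic", "a", "b", idx, one, delta = 0), "positive")
})

test_that("community indices collapse to classical ones without shared communities", {
  net <- example_graph()
  idx <- neighbor_index(net)
  # every node its own community: C(i) n C(x) n C(y) is always empty
  part <- setNames(seq_along(net$nodes), net$nodes)
  solo <- structure(list(partition = part,
                         overlapping = lapply(part, identity),
                         method = "manual", k = NA_integer_, seed = 0L,
                         n_communities = length(part)),
                    class = "community_assignment")
  expect_equal(community_index("ccn", "a", "b", idx, solo),
               classical_index("cn", "a", "b", idx))
  expect_equal(community_index("cra", "a", "b", idx, solo),
               classical_index("rai", "a", "b", idx))
  expect_equal(community_index("wic", "a", "b", idx, solo), 0)  # different partitions
})

test_that("all eight indices match the brute-force oracle on random graphs", {
  delta <- 0.001
  for (seed in 1:40) {
    net <- rand_graph(sample(5:30, 1), runif(1, 0.15, 0.5), seed = 1000 + seed)
    comm <- rand_communities(net, seed = seed)
    pairs <- t(combn(net$nodes, 2))
    if (nrow(pairs) > 25) pairs <- pairs[sample(nrow(pairs), 25), , drop = FALSE]
    lp <- data.frame(drug1 = pairs[, 1], drug2 = pairs[, 2], label = 0L)
    feats <- featurize_topology(lp, net, comm, delta = delta)
    for (r in seq_len(nrow(feats))) {
      o <- bf_topo(net, feats$drug1[r], feats$drug2[r],
                   comm$overlapping, comm$partition, delta)
      got <- unlist(feats[r, names(o)])
      expect_equal(got, o, tolerance = 1e-9,
                   label = paste("seed", seed, feats$drug1[r], feats$drug2[r]))
    }
  }
})

test_that("indices are symmetric in the pair", {
  net <- rand_graph(18, 0.3, seed = 77)
  idx <- neighbor_index(net)
  comm <- rand_communities(net, seed = 77)
  pairs <- t(combn(net$nodes, 2))[sample(153, 20), ]
  for (r in seq_len(nrow(pairs))) {
    x <- pairs[r, 1]; y <- pairs[r, 2]
    for (k in c("cn", "jc", "aai", "pa", "rai")) {
      expect_equal(classical_index(k, x, y, idx), classical_index(k, y, x, idx))
    }
    for (k in c("ccn", "cra", "wic")) {
      expect_equal(community_index(k, x, y, idx, comm),
                   community_index(k, y, x, idx, comm))
    }
  }
})

test_that("bound chain holds on generated instances", {
  for (seed in 1:10) {
    net <- rand_graph(20, 0.3, seed = 300 + seed)
    comm <- rand_communities(net, seed = seed)
    pairs <- t(combn(net$nodes, 2))
    lp <- data.frame(drug1 = pairs[, 1], drug2 = pairs[, 2], label = 0L)
    f <- featurize_topology(lp, net, comm)
    expect_true(all(f$jc >= 0 & f$jc <= 1))
    expect_true(all(f$rai <= f$cn / 2 + 1e-12))
    expect_true(all(f$aai <= f$cn / log(2) + 1e-12))
    expect_true(all(f$ccn >= f$cn))
    expect_true(all(f$cra >= f$rai - 1e-12))
    expect_true(all(f$wic >= 0))
    # every common neighbour has degree >= 2, so aai terms stay finite
    expect_true(all(is.finite(f$aai)))
  }
})

test_that("a single global community gives wic = cn/delta and ccn = 2 cn", {
  net <- rand_graph(12, 0.4, seed = 55)
  one <- single_community(net)
  pairs <- t(combn(net$nodes, 2))
  lp <- data.frame(drug1 = pairs[, 1], drug2 = pairs[, 2], label = 0L)
  f <- featurize_topology(lp, net, one, delta = 0.001)
  nz <- f$cn > 0
  expect_equal(f$wic[nz], f$cn[nz] / (0 + 0.001), tolerance = 1e-9)
  expect_equal(f$ccn, 2 * f$cn)
})

test_that("featurize refuses pairs with endpoints outside the network", {
  net <- example_graph()
  lp <- data.frame(drug1 = c("a", "zz"), drug2 = c("b", "c"), label = 0L)
  expect_error(featurize_topology(lp, net), "absent")
})

test_that("isolated endpoints give all-zero indices", {
  net <- ddi_network(rbind(c("a", "b")), nodes = c("a", "b", "x", "y"))
  lp <- data.frame(drug1 = "x", drug2 = "y", label = 0L)
  f <- featurize_topology(lp, net, single_community(net))
  expect_equal(unlist(f[1, c("cn", "jc", "aai", "pa", "rai", "ccn", "cra", "wic")]),
               setNames(rep(0, 8), c("cn", "jc", "aai", "pa", "rai", "ccn", "cra", "wic")))
})

test_that("feature columns appear in the canonical order", {
  net <- example_graph()
  lp <- data.frame(drug1 = "a", drug2 = "b", label = 1L)
  f <- featurize_topology(lp, net)
  expect_equal(names(f)[4:11], c("cn", "jc", "aai", "pa", "rai", "ccn", "cra", "wic"))
})
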