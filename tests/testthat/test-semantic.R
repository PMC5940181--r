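test_that("IDF weights follow ln(|D|/n_t)", {
  cat10 <- attribute_catalog(
    data.frame(drug_id = rep(sprintf("d%02d", 1:10), each = 1),
               code = rep("A", 10)), channel = "ATC")
  expect_equal(unname(compute_idf(cat10)["A"]), 0)  # code in every drug

  cat3 <- attribute_catalog(
    data.frame(drug_id = c("d1", "d2", "d3"), code = c("A", "B", "C")), "ATC")
  expect_equal(unname(compute_idf(cat3)["A"]), log(3), tolerance = 1e-12)

  # monotone non-increasing in n_t, exhaustively for |D| <= 20
  for (nd in 2:20) {
    drugs <- sprintf("d%02d", 1:nd)
    rows <- do.call(rbind, lapply(1:nd, function(nt) {
      data.frame(drug_id = drugs[1:nt], code = paste0("c", nt))
    }))
    w <- compute_idf(attribute_catalog(rows, "MESH", drugs = drugs))
    w <- w[paste0("c", 1:nd)]
    expect_true(all(diff(w) <= 1e-12))
    expect_equal(unname(w[nd]), 0)
  }
})

test_that("IDF cosine reproduces the worked example and its identities", {
  cat3 <- attribute_catalog(
    data.frame(drug_id = c("d1", "d1", "d2", "d3"),
               code = c("A", "B", "A", "C")), "ATC")
  w_a <- log(3 / 2); w_b <- log(3)
  s <- idf_cosine("d1", "d2", cat3)
  expect_equal(as.numeric(s), w_a^2 / (sqrt(w_a^2 + w_b^2) * w_a), tolerance = 1e-9)
  expect_equal(as.numeric(s), 0.3462416, tolerance = 1e-6)  # = ln(1.5)/sqrt(ln(1.5)^2+ln(3)^2)
  expect_false(attr(s, "missing"))
  # identical nonempty sets -> 1; disjoint -> 0
  cat2 <- attribute_catalog(
    data.frame(drug_id = c("d1", "d2", "d3"), code = c("A", "A", "B")), "ATC")
  expect_equal(as.numeric(idf_cosine("d1", "d2", cat2)), 1)
  expect_equal(as.numeric(idf_cosine("d1", "d3", cat2)), 0)
  # absent drug takes the missing path
  m <- idf_cosine("d1", "nope", cat2)
  expect_equal(as.numeric(m), 0)
  expect_true(attr(m, "missing"))
})

test_that("IDF cosine matches explicit vector arithmetic on random catalogs", {
  for (seed in 1:10) {
    set.seed(seed)
    drugs <- sprintf("d%02d", 1:12)
    vocab <- paste0("c", 1:15)
    rows <- do.call(rbind, lapply(drugs, function(d) {
      data.frame(drug_id = d, code = sample(vocab, sample(1:6, 1)))
    }))
    cat_ <- attribute_catalog(rows, "ADE", drugs = drugs)
    w <- compute_idf(cat_)
    # oracle: build the weighted vectors explicitly
    vec <- function(d) {
      v <- setNames(numeric(length(cat_$vocab)), cat_$vocab)
      v[cat_$sets[[d]]] <- w[cat_$sets[[d]]]
      v
    }
    for (i in 1:8) {
      xy <- sample(drugs, 2)
      vx <- vec(xy[1]); vy <- vec(xy[2])
      expected <- if (sum(vx^2) == 0 || sum(vy^2) == 0) 0 else
        sum(vx * vy) / sqrt(sum(vx^2) * sum(vy^2))
      expect_equal(as.numeric(idf_cosine(xy[1], xy[2], cat_, w)), expected,
                   tolerance = 1e-9)
    }
  }
})

test_that("cosine is unaffected by vocabulary codes neither drug has", {
  base <- data.frame(drug_id = c("d1", "d1", "d2", "d3"),
                     code = c("A", "B", "A", "C"))
  # same |D| and same n_t for A and B; d3 just gains codes neither d1 nor d2 has
  c1 <- attribute_catalog(base, "ATC")
  c2 <- attribute_catalog(rbind(base, data.frame(drug_id = "d3", code = c("Z1", "Z2"))), "ATC")
  expect_equal(as.numeric(idf_cosine("d1", "d2", c1)),
               as.numeric(idf_cosine("d1", "d2", c2)), tolerance = 1e-12)
})

test_that("first-level truncation collapses hierarchical codes", {
  cat_ <- attribute_catalog(
    data.frame(drug_id = c("d1", "d2"), code = c("A01BC", "A99")), "ATC",
    first_level = TRUE)
  expect_equal(cat_$vocab, "A")
  expect_equal(as.numeric(idf_cosine("d1", "d2", cat_)), 0)  # zero IDF weight
})

test_that("tanimoto reproduces direct formula values", {
  fp <- fingerprint_catalog(data.frame(drug_id = c("x", "y", "z", "w"),
                                       bits = c("1100", "1010", "1100", "0000")))
  expect_equal(as.numeric(tanimoto("x", "y", fp)), 1 / 3, tolerance = 1e-12)
  expect_equal(as.numeric(tanimoto("x", "z", fp)), 1)
  zz <- tanimoto("w", "w", fp)
  expect_equal(as.numeric(zz), 0)
  expect_true(attr(zz, "missing"))
  expect_error(fingerprint_catalog(data.frame(drug_id = c("a", "b"),
                                              bits = c("110", "1100"))), "length")
})

test_that("tanimoto matches per-bit counting and Jaccard on supports", {
  set.seed(42)
  nb <- 128
  drugs <- sprintf("d%03d", 1:60)
  bits <- matrix(runif(60 * nb) < 0.15, 60, nb, dimnames = list(drugs, NULL))
  fp <- fingerprint_catalog(bits * 1L)
  for (i in 1:200) {
    xy <- sample(drugs, 2)
    bx <- bits[xy[1], ]; by <- bits[xy[2], ]
    a <- 0; b <- 0; cc <- 0
    for (k in seq_len(nb)) {  # naive per-bit loop
      a <- a + bx[k]; b <- b + by[k]; cc <- cc + (bx[k] && by[k])
    }
    expected <- if (a + b - cc == 0) 0 else cc / (a + b - cc)
    got <- as.numeric(tanimoto(xy[1], xy[2], fp))
    expect_equal(got, expected, tolerance = 1e-12)
    # Jaccard equivalence on supported-bit sets
    sx <- which(bx); sy <- which(by)
    jac <- if (length(union(sx, sy)) == 0) 0 else
      length(intersect(sx, sy)) / length(union(sx, sy))
    expect_equal(got, jac, tolerance = 1e-12)
  }
})

test_that("semantic featurization appends the four columns with missingness flags", {
  ds <- generate_ddi_data(synth_config(n_drugs = 60, seed = 9,
                                       missingness = c(atc = 0.2, mesh = 0, ade = 0, chem = 0.2)))
  bp <- balanced_pairs(ds$network, seed = 2)
  f <- featurize_semantic(bp, atc = ds$atc, mesh = ds$mesh, ade = ds$ade, chem = ds$chem)
  expect_equal(names(f)[4:7], c("atc", "chem", "mesh", "ade"))
  expect_true(all(f$atc >= 0 & f$atc <= 1))
  miss <- attr(f, "missingness")
  expect_named(miss, c("atc", "chem", "mesh", "ade"))
  expect_equal(unname(miss[c("mesh", "ade")]), c(0L, 0L))
  # spot-check rows against the single-pair evaluation path
  w_mesh <- compute_idf(ds$mesh)
  for (r in sample(nrow(f), 10)) {
    expect_equal(f$mesh[r],
                 as.numeric(idf_cosine(f$drug1[r], f$drug2[r], ds$mesh, w_mesh)),
                 tolerance = 1e-9)
    expect_equal(f$chem[r],
                 as.numeric(tanimoto(f$drug1[r], f$drug2[r], ds$chem)),
                 tolerance = 1e-9)
  }
})

test_that("semantic similarities are symmetric and duplicates score 1 everywhere", {
  ds <- generate_ddi_data(synth_config(n_drugs = 30, seed = 5, missingness = c(
    atc = 0, mesh = 0, ade = 0, chem = 0)))
  d1 <- ds$network$nodes[1]
  dup <- data.frame(drug1 = d1, drug2 = d1, label = 1L)
  f <- featurize_semantic(dup, ds$atc, ds$mesh, ds$ade, ds$chem)
  expect_equal(unlist(f[1, c("atc", "chem", "mesh", "ade")]),
               setNames(rep(1, 4), c("atc", "chem", "mesh", "ade")), tolerance = 1e-12)
  a <- ds$network$nodes[2]; b <- ds$network$nodes[3]
  fwd <- featurize_semantic(data.frame(drug1 = a, drug2 = b, label = 0L),
                            ds$atc, ds$mesh, ds$ade, ds$chem)
  rev <- featurize_semantic(data.frame(drug1 = b, drug2 = a, label = 0L),
                            ds$atc, ds$mesh, ds$ade, ds$chem)
  expect_equal(unlist(fwd[1, c("atc", "chem", "mesh", "ade")]),
               unlist(rev[1, c("atc", "chem", "mesh", "ade")]), tolerance = 1e-12)
})
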