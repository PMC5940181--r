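#' Per-drug attribute catalogs (ATC / MeSH / side-effect codes)
#'
#' An attribute catalog maps each drug to the set of codes annotated to it in
#' one vocabulary channel. Drugs with an explicitly empty code set are
#' distinguishable from drugs absent from the catalog (the latter take the
#' missing-data path in similarity computation).
#'
#' @param x A data frame with columns `drug_id` and `code` (long format, one
#'   row per annotation).
#' @param channel Channel tag: `"ATC"`, `"MESH"` or `"ADE"`.
#' @param drugs Optional character vector of drugs to include with empty code
#'   sets if they carry no annotation rows.
#' @param first_level If `TRUE`, truncate each code to its first character
#'   before building the catalog (the top level of a hierarchical coding such
#'   as ATC's 14 anatomical main groups). Default `FALSE`: full codes.
#' @return An object of class `attribute_catalog`: list with `sets` (named
#'   list of character vectors), `vocab`, `channel`, `drugs`.
#' @export
attribute_catalog <- function(x, channel = c("ATC", "MESH", "ADE"),
                              drugs = NULL, first_level = FALSE) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(x), all(c("drug_id", "code") %in% names(x)))
  code <- as.character(x$code)
  if (first_level) code <- substr(code, 1L, 1L)
  ids <- as.character(x$drug_id)
  sets <- lapply(split(code, ids), function(v) sort(unique(v)))
  for (d in setdiff(as.character(drugs), names(sets))) sets[[d]] <- character(0L)
  sets <- sets[order(names(sets), method = "radix")]
  structure(list(sets = sets, vocab = sort(unique(unlist(sets))),
                 channel = channel, drugs = names(sets)),
            class = "attribute_catalog")
}

#' Read an attribute catalog from a long TSV file
#'
#' Expected columns: `drug_id`, `code` (header row required).
#'
#' @param path File path.
#' @inheritParams attribute_catalog
#' @return An `attribute_catalog`.
#' @export
read_attribute_catalog <- function(path, channel = c("ATC", "MESH", "ADE"),
                                   first_level = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  attribute_catalog(d, channel = channel, first_level = first_level)
}

#' @export
print.attribute_catalog <- function(x, ...) {
  cat(sprintf("<attribute_catalog> %s: %d drugs, %d codes\n",
              x$channel, length(x$drugs), length(x$vocab)))
  invisible(x)
}

#' Inverse document frequency weights for an attribute catalog
#'
#' `IDF(t) = ln(|D| / n_t)` where `|D|` is the number of drugs in the
#' catalog (channel-specific, not the network's node count) and `n_t` the
#' number of drugs annotated with code `t`. Codes carried by every drug get
#' weight 0; rarer codes get larger weights. The logarithm base is immaterial
#' for the downstream cosine similarity (it rescales all weights uniformly);
#' the natural log is used so stored weights are reproducible.
#'
#' @param catalog An [attribute_catalog()] with at least one drug.
#' @return An object of class `idf_weights`: named numeric vector of weights
#'   with attribute `n_drugs`.
#' @export
compute_idf <- function(catalog) {
  stopifnot(inherits(catalog, "attribute_catalog"))
  n_d <- length(catalog$drugs)
  if (n_d < 1L) stop("catalog has no drugs")
  counts <- table(factor(unlist(catalog$sets), levels = catalog$vocab))
  if (any(counts == 0L)) stop("inconsistent catalog: vocabulary code with zero occurrences")
  w <- log(n_d / as.numeric(counts))
  names(w) <- catalog$vocab
  structure(w, n_drugs = n_d, class = c("idf_weights", "numeric"))
}

#' IDF-weighted cosine similarity between two drugs' code sets
#'
#' Each drug is a binary vector over the catalog vocabulary, weighted by the
#' IDF of each code; the similarity is the cosine of the two weighted
#' vectors. When either drug is absent from the catalog, or either weighted
#' vector has zero norm, the similarity is 0 and the result carries attribute
#' `missing = TRUE`.
#'
#' @param x,y Drug identifiers.
#' @param catalog An [attribute_catalog()].
#' @param weights IDF weights from [compute_idf()]; computed from `catalog`
#'   if missing.
#' @return A number in `[0, 1]` with logical attribute `missing`.
#' @export
idf_cosine <- function(x, y, catalog, weights = NULL) {
  stopifnot(inherits(catalog, "attribute_catalog"))
  if (is.null(weights)) weights <- compute_idf(catalog)
  sx <- catalog$sets[[as.character(x)]]
  sy <- catalog$sets[[as.character(y)]]
  if (is.null(sx) || is.null(sy)) {
    return(structure(0, missing = TRUE))
  }
  nx <- sqrt(sum(weights[sx]^2))
  ny <- sqrt(sum(weights[sy]^2))
  if (nx == 0 || ny == 0) {
    return(structure(0, missing = TRUE))
  }
  dot <- sum(weights[intersect(sx, sy)]^2)
  structure(min(1, dot / (nx * ny)), missing = FALSE)
}

#' Binary chemical fingerprint catalog
#'
#' Holds one fixed-length binary fingerprint per drug (1024 bits by default,
#' the length of standard extended-connectivity fingerprints). The package
#' consumes precomputed bitstrings; producing fingerprints from structures is
#' left to a chemistry toolkit upstream.
#'
#' @param x Either a data frame with columns `drug_id` and `bits` (each a
#'   string of `0`/`1` characters, all the same length) or a logical/0-1
#'   matrix with drugs as named rows.
#' @param nbits Expected bit length; checked against the data when supplied.
#' @return An object of class `fingerprint_catalog`: list with `bits`
#'   (logical matrix, drugs x bits), `nbits`, `drugs`.
#' @export
fingerprint_catalog <- function(x, nbits = NULL) {
  if (is.data.frame(x)) {
    stopifnot(all(c("drug_id", "bits") %in% names(x)))
    s <- as.character(x$bits)
    lens <- nchar(s)
    if (length(unique(lens)) > 1L) stop("fingerprints have differing lengths")
    if (any(grepl("[^01]", s))) stop("fingerprints must contain only 0/1 characters")
    m <- matrix(unlist(strsplit(s, "")) == "1", nrow = length(s), byrow = TRUE)
    rownames(m) <- as.character(x$drug_id)
  } else {
    m <- x == 1
    if (is.null(rownames(m))) stop("fingerprint matrix needs drug ids as row names")
  }
  if (!is.null(nbits) && ncol(m) != nbits) {
    stop(sprintf("expected %d bits, got %d", nbits, ncol(m)))
  }
  structure(list(bits = m, nbits = ncol(m), drugs = rownames(m)),
            class = "fingerprint_catalog")
}

#' Read fingerprints from a TSV file
#'
#' Expected columns: `drug_id`, `bits` (header row required; `bits` is a
#' fixed-length 0/1 string).
#'
#' @param path File path.
#' @param nbits Optional expected bit length.
#' @return A `fingerprint_catalog`.
#' @export
read_fingerprints <- function(path, nbits = NULL) {
  d <- utils::read.delim(path, colClasses = "character")
  fingerprint_catalog(d, nbits = nbits)
}

#' @export
print.fingerprint_catalog <- function(x, ...) {
  cat(sprintf("<fingerprint_catalog> %d drugs x %d bits\n", length(x$drugs), x$nbits))
  invisible(x)
}

#' Tanimoto similarity between two drugs' fingerprints
#'
#' `c / (a + b - c)` where `a` and `b` are the numbers of set bits in the two
#' fingerprints and `c` the number of bits set in both; equal to the Jaccard
#' similarity of the supported-bit sets. Two all-zero fingerprints, or a drug
#' absent from the catalog, give similarity 0 with attribute `missing = TRUE`.
#'
#' @param x,y Drug identifiers.
#' @param catalog A [fingerprint_catalog()].
#' @return A number in `[0, 1]` with logical attribute `missing`.
#' @export
tanimoto <- function(x, y, catalog) {
  stopifnot(inherits(catalog, "fingerprint_catalog"))
  px <- match(as.character(x), catalog$drugs)
  py <- match(as.character(y), catalog$drugs)
  if (is.na(px) || is.na(py)) {
    return(structure(0, missing = TRUE))
  }
  bx <- catalog$bits[px, ]
  by <- catalog$bits[py, ]
  cc <- sum(bx & by)
  denom <- sum(bx) + sum(by) - cc
  if (denom == 0) {
    return(structure(0, missing = TRUE))
  }
  structure(cc / denom, missing = FALSE)
}

# Vectorized IDF-cosine over pair endpoint vectors; returns value + missing flag
idf_cosine_pairs <- function(d1, d2, catalog, weights) {
  drugs <- catalog$drugs
  vocab <- catalog$vocab
  w <- as.numeric(weights)
  # drugs x vocab weighted incidence matrix
  m <- matrix(0, nrow = length(drugs), ncol = length(vocab),
              dimnames = list(drugs, vocab))
  lens <- vapply(catalog$sets, length, 1L)
  if (sum(lens) > 0L) {
    ri <- rep(seq_along(drugs), lens)
    ci <- match(unlist(catalog$sets), vocab)
    m[cbind(ri, ci)] <- w[ci]
  }
  nrm <- sqrt(rowSums(m^2))
  p1 <- match(d1, drugs)
  p2 <- match(d2, drugs)
  miss <- is.na(p1) | is.na(p2)
  val <- numeric(length(d1))
  ok <- which(!miss)
  if (length(ok) > 0L) {
    dot <- rowSums(m[p1[ok], , drop = FALSE] * m[p2[ok], , drop = FALSE])
    denom <- nrm[p1[ok]] * nrm[p2[ok]]
    zero <- denom == 0
    val[ok] <- ifelse(zero, 0, pmin(1, dot / ifelse(zero, 1, denom)))
    miss[ok[zero]] <- TRUE
  }
  list(value = val, missing = miss)
}

tanimoto_pairs <- function(d1, d2, catalog) {
  p1 <- match(d1, catalog$drugs)
  p2 <- match(d2, catalog$drugs)
  miss <- is.na(p1) | is.na(p2)
  val <- numeric(length(d1))
  ok <- which(!miss)
  if (length(ok) > 0L) {
    b1 <- catalog$bits[p1[ok], , drop = FALSE]
    b2 <- catalog$bits[p2[ok], , drop = FALSE]
    cc <- rowSums(b1 & b2)
    denom <- rowSums(b1) + rowSums(b2) - cc
    zero <- denom == 0
    val[ok] <- ifelse(zero, 0, cc / ifelse(zero, 1, denom))
    miss[ok[zero]] <- TRUE
  }
  list(value = val, missing = miss)
}

#' Append the four semantic feature columns to a labelled pair set
#'
#' Columns `atc`, `chem`, `mesh`, `ade` are appended in that order. A pair
#' for which a channel has no data (drug absent from the catalog, or
#' zero-norm vector) gets the imputed similarity 0 for that channel;
#' missingness is data, not an error, and a per-channel summary of imputed
#' pair counts is attached as attribute `missingness`.
#'
#' @param pairs A `labeled_pairs` data frame.
#' @param atc,mesh,ade [attribute_catalog()] objects for the three code
#'   channels (any may be `NULL`, in which case the whole column is 0 and
#'   flagged missing).
#' @param chem A [fingerprint_catalog()] (or `NULL`).
#' @return `pairs` with the four columns appended and attribute
#'   `missingness` (named integer vector of imputed pair counts).
#' @export
featurize_semantic <- function(pairs, atc = NULL, mesh = NULL, ade = NULL,
                               chem = NULL) {
  stopifnot(is.data.frame(pairs))
  d1 <- as.character(pairs$drug1)
  d2 <- as.character(pairs$drug2)
  np <- length(d1)
  blank <- list(value = numeric(np), missing = rep(TRUE, np))
  chan <- list(
    atc = if (is.null(atc)) blank else idf_cosine_pairs(d1, d2, atc, compute_idf(atc)),
    chem = if (is.null(chem)) blank else tanimoto_pairs(d1, d2, chem),
    mesh = if (is.null(mesh)) blank else idf_cosine_pairs(d1, d2, mesh, compute_idf(mesh)),
    ade = if (is.null(ade)) blank else idf_cosine_pairs(d1, d2, ade, compute_idf(ade))
  )
  out <- pairs
  for (nm in names(chan)) out[[nm]] <- chan[[nm]]$value
  attr(out, "missingness") <- vapply(chan, function(ch) sum(ch$missing), 1L)
  class(out) <- class(pairs)
  out
}
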