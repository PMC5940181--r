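# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a root seed
#'
#' Every stochastic stage of the pipeline draws its seed from the single
#' user-supplied root seed and the stage's name, so that adding or removing a
#' stage never perturbs the randomness of the others.
#'
#' @param seed Integer root seed.
#' @param stage Character stage name.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(paste(stage, collapse = "/"))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Canonical within-pair order: lexicographically smaller identifier first.
canonical_pairs <- function(a, b) {
  swap <- as.character(b) < as.character(a)
  cbind(ifelse(swap, b, a), ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  m <- canonical_pairs(a, b)
  paste(m[, 1L], m[, 2L], sep = "\r")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
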