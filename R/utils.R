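# Shared internal helpers: seeding, RNG hygiene, numeric utilities.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package randomness flows through this, so a
# single top-level seed fully determines every artifact.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific 31-bit seed from a base seed and a text tag, so each
# pipeline stage consumes an independent, reproducible stream.
#' @keywords internal
derive_seed <- function(base_seed, tag) {
  h <- as.double(base_seed) %% 2147483647
  for (k in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
sigmoid <- function(x) stats::plogis(x)

# Clip probabilities away from {0, 1} so cross-entropy stays finite.
#' @keywords internal
clip_probs <- function(p, eps = 1e-7) {
  pmin(pmax(p, eps), 1 - eps)
}

#' @keywords internal
glorot <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
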