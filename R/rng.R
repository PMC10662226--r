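## Deterministic seed derivation. Every generator draws from a stream seeded
## by a child seed derived from (base seed, structural keys), so adding
## replicates or data types never perturbs already-generated values, and all
## derived seeds stay below 2^31.

.M31 <- 2147483647

.keyHash <- function(key) {
  if (is.character(key)) {
    h <- 0
    for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% .M31
    h
  } else {
    as.numeric(key) %% .M31
  }
}

#' Derive a deterministic child seed
#'
#' Mixes a base seed with an arbitrary sequence of structural keys (strings
#' or integers) through a multiplicative-congruential hash, returning an
#' integer in [1, 2^31 - 2]. Used internally so that each leaf and each data
#' type has its own reproducible random stream.
#'
#' @param seed Integer base seed.
#' @param ... Structural keys (character or integer scalars).
#' @return A single integer seed.
#' @export
childSeed <- function(seed, ...) {
  x <- .keyHash(seed)
  for (k in list(...)) {
    x <- (x * 48271 + .keyHash(k) + 1) %% .M31
  }
  as.integer(x %% (.M31 - 2) + 1)
}

## evaluate expr with a locally-seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
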