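# Deterministic seed derivation so every stage of a pipeline or benchmark can
# be reproduced in isolation from one root seed.

MODULUS <- 2147483647  # 2^31 - 1; derived seeds stay valid 32-bit integers

hash_tag <- function(tag) {
  codes <- utf8ToInt(as.character(tag))
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% MODULUS
  h
}

#' Derive a child seed from a root seed and a sequence of tags
#'
#' Child seeds make each dataset, run and algorithm stage independently
#' reproducible: the same `(root, tags...)` always yields the same seed, and
#' distinct tag paths yield (with overwhelming probability) distinct seeds.
#'
#' @param root integer root seed.
#' @param ... tags (strings or integers) identifying the stage, e.g.
#'   `derive_seed(42, "dataset", 3, "noise", "rna")`.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "dataset", 1) != derive_seed(42, "dataset", 2)
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  h <- as.numeric(root) %% MODULUS
  # multiplier kept small so h * mult stays below 2^53 (exact in doubles)
  for (tag in list(...)) h <- (h * 69069 + hash_tag(tag)) %% MODULUS
  as.integer(h %% (MODULUS - 2) + 1)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
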