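# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded components never perturb each other.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed and a stream index
#'
#' Deterministic arithmetic stream splitter; keeps derived seeds inside the
#' 32-bit integer range so they are always valid `set.seed()` inputs.
#'
#' @param seed Master integer seed.
#' @param stream Non-negative integer stream index (may be a vector).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  # two rounds of a multiplicative congruential mix per stream index
  out <- vapply(as.numeric(stream), function(k) {
    x <- (s * 48271 + k * 16807 + 1) %% m
    x <- (x * 69621 + 12345) %% m
    x
  }, numeric(1))
  as.integer(out)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

relu <- function(x) {
  x * (x > 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
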