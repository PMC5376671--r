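# Internal helpers: seed management and small validators.

#' @importFrom stats runif sd var setNames
#' @importFrom utils head tail write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps all randomness traceable to the
# seeds the caller passes in.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive `n` child seeds from a master seed. Used so replicates, batches and
# screen topologies each get an independent, individually reproducible stream.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

# Nearly-integer ratio check for step/interval alignment.
is_multiple <- function(x, of, tol = 1e-8) {
  r <- x / of
  abs(r - round(r)) < tol
}
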