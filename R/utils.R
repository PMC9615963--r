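#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had. All exported generators funnel through this
# so that they are pure functions of their arguments.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a root seed
#'
#' Deterministically splits one root seed into per-stage / per-replicate
#' seeds so that multi-part fixtures are reproducible from a single integer.
#' The result always fits in a 32-bit signed integer.
#'
#' @param root Root seed (integer).
#' @param k Child index (integer, may be a vector).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(root, k) {
  stopifnot(is.numeric(root), all(is.finite(k)))
  # multiplicative hash mod a Mersenne prime; avoids 0 which set.seed allows
  # but which collides with the unset state in some helper logic
  as.integer((abs(root) * 48271 + as.numeric(k) * 16807) %% 2147483646 + 1)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
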