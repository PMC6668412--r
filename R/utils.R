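#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a new integer
#' seed, so that adding or reordering pipeline stages does not silently
#' shift the random stream of the others. The result is always in
#' `[1, 2^31 - 1]`. The command-line pipeline uses this to give each
#' stochastic stage (panel generation, simulation, ranking) its own
#' stream derived from one `--seed`.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

# Checks that each row of q lies on the probability simplex.
is_simplex_rows <- function(q, tol = 1e-8) {
  all(q >= -tol) && all(abs(rowSums(q) - 1) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
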