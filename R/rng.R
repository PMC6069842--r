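# Seed handling.
#
# Every stochastic operation takes an integer seed and runs inside
# with_seed(), which restores the caller's RNG state afterwards, so package
# functions never clobber a user's random stream. Operations that are part
# of a larger simulation derive sub-stream seeds from the one global seed by
# fixed per-operation offsets, so adding a new operation never perturbs the
# draws of existing ones.

.MODULUS <- 2147483563L  # < 2^31, keeps derived seeds valid R integers

#' Derive a deterministic sub-stream seed
#'
#' @param seed integer master seed.
#' @param offset fixed non-negative integer offset identifying the operation.
#' @return An integer seed in `[1, 2^31)`.
#' @keywords internal
#' @noRd
sub_seed <- function(seed, offset) {
  s <- (as.double(seed) %% .MODULUS) + 1
  as.integer((s * 48271 + as.double(offset) * 1000003) %% .MODULUS) + 1L
}

#' Evaluate an expression under a fixed seed, restoring RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
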