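#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation helpers do not disturb
# the session RNG. seed = NULL runs the code under the current RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic seed-splitting scheme used throughout the simulators: every
#' sub-stream (one trajectory, one image, one cell) receives
#' `(seed + 1000003 * index) mod (2^31 - 1)` so that a single master seed
#' reproduces the whole simulated data set bit for bit while sub-streams stay
#' decorrelated.
#'
#' @param seed master seed (single integer-like value).
#' @param index non-negative integer index of the sub-stream.
#' @return an integer seed.
#' @export
split_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  as.integer((as.double(seed) + 1000003 * as.double(index)) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

# summary.lm without the "essentially perfect fit" warning, which fires on
# the exact (noise-free) fixtures used to validate the regressions
quiet_lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}
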