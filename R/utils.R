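# Shared small helpers.

#' Round half away from zero
#'
#' Base \code{round()} uses round-half-to-even; clinical reports round
#' half-up, and the package's printed percentages must match that
#' convention (e.g. 80.85 -> 80.9, not 80.8).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# percentage on the 0-100 scale at a given printed precision
as_pct <- function(x, digits = 0) round_half_up(100 * x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() without the call, consistent error class for data problems
abort_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("phenocuff_data_error", "error")))
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("phenocuff_config_error", "error")))
}

# Evaluate expr with a private RNG stream seeded from `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
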