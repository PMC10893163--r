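# Seed plumbing. Stochastic entry points take an explicit integer seed; we
# set it locally and restore the caller's RNG state on exit so package calls
# never disturb the user's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a stage sub-seed from a master seed
#'
#' Deterministic counter-based fan-out used by the trial engine and the
#' pipeline so that every stochastic stage (each arm of each replicate
#' study, the dissolution generator, ...) has its own logged seed. Results
#' stay within the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param ... One or more non-negative integer counters (stage, replicate,
#'   arm, ...).
#' @return An integer seed.
#' @export
sub_seed <- function(seed, ...) {
  counters <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in counters) {
    # affine hash step, kept exactly representable in doubles
    x <- (x * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}
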