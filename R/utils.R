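#' @importFrom stats coef lm median pt qnorm rnorm runif rlnorm rpois sd t.test
#'   var p.adjust rgamma setNames complete.cases
#' @importFrom utils head combn
#' @importFrom methods is
#' @importFrom rlang .data
NULL

# Run `code` under a fixed RNG state, restoring the caller's state afterwards.
# All package randomness flows through this so generators are pure in (params, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Wrap x (hours) into (-period/2, period/2]; a half-cycle shift reports as +T/2.
wrap_half_period <- function(x, period) {
  y <- x %% period
  ifelse(y > period / 2, y - period, y)
}

# Wrap x (hours) into [0, period).
wrap_period <- function(x, period) x %% period

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
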