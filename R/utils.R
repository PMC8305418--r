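# Internal helpers shared across modules.

#' @importFrom stats median rnorm rbeta rpois rgamma rlnorm runif sd setNames
#' @importFrom utils read.delim write.table modifyList
NULL

# Derive an independent RNG stream from a master seed. Components of the
# simulator each draw from their own stream so that enlarging one component
# does not perturb the draws of another. Kept below 2^31 - 1.
stream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  as.integer((abs(seed) %% 1800000L) * 1000L + component)
}

# Evaluate `expr` under a component stream without disturbing the caller's
# RNG state.
with_stream <- function(seed, component, expr) {
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
  set.seed(stream_seed(seed, component))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform message prefix so pipeline logs are greppable.
sd_log <- function(...) message("[screendep] ", ...)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == round(x)
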