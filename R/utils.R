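#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis rnorm runif rbinom sd quantile lm coef predict
#'   kmeans prcomp setNames aggregate optimize binom.test complete.cases
#' @importFrom utils head tail modifyList
NULL

# Independent reproducible RNG streams.
#
# R has a single global generator; interleaving draws from the environment,
# the agent and the replay sampler would make determinism depend on call
# order. A stream object freezes its own `.Random.seed` and swaps it in for
# the duration of a draw, so each consumer advances independently.

#' Create an independent random-number stream
#'
#' @param seed Integer seed for this stream.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  structure(e, class = "rng_stream")
}

#' Evaluate an expression using a given stream's generator state
#'
#' The global generator state is restored afterwards; the stream advances.
#'
#' @param stream An `rng_stream`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# Derive a child seed from a parent seed and a label, stably across sessions.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647L)
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite numeric value.", name),
          class = "loadctrl_invalid_input")
  }
  invisible(as.numeric(x))
}

check_range <- function(x, name, lo = -Inf, hi = Inf) {
  check_scalar(x, name)
  if (x < lo || x > hi) {
    abort(sprintf("`%s` must lie in [%s, %s], got %s.", name, lo, hi, x),
          class = "loadctrl_invalid_input")
  }
  invisible(as.numeric(x))
}

clip01 <- function(x) pmin(1, pmax(0, x))
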