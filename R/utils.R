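# shared helpers: seeded substreams, argument checks

#' Derive a named random-seed substream from a global seed
#'
#' All stochastic stages draw their seeds from one global seed through named
#' substreams, so each stage is independently re-runnable and the whole
#' pipeline is reproducible end to end.
#'
#' @param seed integer global seed.
#' @param name character stream label, e.g. "folds", "search/gbm".
#' @return an integer seed in [0, 2^31).
#' @examples
#' deriveSeed(42, "folds")
#' @export
deriveSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

.assertScalarNumber <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop("'", name, "' must be a single number >= ", min, call. = FALSE)
  }
  invisible(x)
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop("'", name, "' must be TRUE or FALSE", call. = FALSE)
  }
  invisible(x)
}

# run an expression with a local RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
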