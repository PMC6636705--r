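#' Derive a child seed for a named component stream
#'
#' All generators in the package take an explicit integer seed. Composite
#' simulations (a whole subject, a whole cohort) derive one child seed per
#' component from a single root seed so that every sub-stream is reproducible
#' in isolation, and record the derivation in their output metadata. The
#' derivation is a small multiplicative hash kept strictly below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed integer root seed.
#' @param stream character label of the component stream.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "spikes")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- seed %% m
  for (k in utf8ToInt(stream)) {
    h <- (h * 69069 + k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL leaves the current stream in place.
local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(seed)
  expr
}

stop_if_not_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}
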