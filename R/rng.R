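#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' One integer seed drives every stochastic stage of the package. Each stage
#' draws from its own named substream so that, for example, tract simulation
#' can be re-run without disturbing the haplogroup assignment stream. The
#' substream seed is a deterministic polynomial hash of `(seed, name)` folded
#' into the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the substream (e.g. `"tracts"`).
#' @return an integer seed suitable for [set.seed()].
#' @examples
#' substream_seed(7, "tracts")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(name), length(name) == 1L, nzchar(name))
  m <- 2147483629  # prime < 2^31
  h <- as.double(seed) %% m
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  as.integer(h)
}

# Run `expr` under a seeded RNG without clobbering the caller's RNG state.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
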