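#' Derive a reproducible substream seed
#'
#' Simulation runs fan a single master seed out into independent, named
#' substreams (one per population, sample size, replicate, stage, ...), so
#' that any single cell of a study grid can be re-run in isolation and match
#' the full run. The derivation is a small multiplicative hash over the
#' integer indices supplied in `...`, reduced modulo the Mersenne prime
#' 2^31 - 1 so the result is always a valid 32-bit R seed.
#'
#' @param master Integer master seed.
#' @param ... Integer indices naming the substream (e.g. population index,
#'   sample-size index, replicate number). Order matters.
#' @return A single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(1, 3, 25, 7)
#' @export
substream_seed <- function(master, ...) {
  ids <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  s <- (abs(as.double(master)) %% 2147483647)
  for (id in c(length(ids), ids)) {
    # doubles stay below 2^53 here, so the arithmetic is exact
    s <- (s * 48271 + (abs(as.double(id)) %% 2147483647) * 7919 + 1) %%
      2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
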