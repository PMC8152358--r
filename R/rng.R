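#' Derive a reproducible sub-stream seed
#'
#' All stochastic entry points in cpforage take a single integer seed and
#' derive independent per-stream seeds from it, so that e.g. adding birds
#' to a simulation does not perturb the isotope draws. Stream labels are
#' fixed strings; the mapping is a documented affine hash kept below
#' 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stream character stream label (e.g. `"tracks"`, `"dives"`).
#' @param index optional integer sub-index (e.g. bird number).
#' @return an integer seed.
#' @export
stream_seed <- function(seed, stream, index = 0L) {
  streams <- c(
    tracks = 11L, dives = 23L, immersion = 29L, isotope = 37L,
    prey = 41L, klepto = 43L, morpho = 47L, hmm_init = 53L,
    gmm_init = 59L, sim = 61L, misc = 67L
  )
  off <- streams[stream]
  if (is.na(off)) stop("unknown RNG stream label: ", stream)
  as.integer((as.double(seed) * 7919 + off * 104729 + index * 7907) %%
               2147483647)
}

# Evaluate expr under a local RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
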