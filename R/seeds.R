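#' Split a master seed into independent child seeds
#'
#' All stochastic stages of the pipeline draw their seeds from one master
#' seed so that a whole run is reproducible from a single integer.  Child
#' seeds are drawn from R's RNG seeded with the master, which keeps them
#' below `.Machine$integer.max`.
#'
#' @param seed Master seed (single integer).
#' @param n Number of child seeds.
#' @return Integer vector of `n` child seeds.
#' @export
#' @examples
#' split_seed(42, 3)
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# set the RNG only when a seed is supplied
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
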