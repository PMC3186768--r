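#' Derive a stage seed from a master seed
#'
#' All stochastic stages (external-set sampling, train/test splitting,
#' cross-validation folds, synthetic data generation) draw their seed from one
#' master seed through a named stream, so a single \code{--seed} reproduces
#' every artifact bit-for-bit while keeping the streams independent.
#'
#' @param master Integer master seed.
#' @param tag Character stream name (e.g. \code{"split"}, \code{"folds"}).
#' @param index Optional integer (e.g. run number) folded into the stream.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(master, tag, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 48271 + h * 7919 + index * 104729) %%
               2147483647)
}
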