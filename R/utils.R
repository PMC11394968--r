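#' Derive a named RNG substream seed
#'
#' All internal randomness flows from one user-facing seed through named
#' substreams: the seed is spread by a Lehmer step and offset by a tag
#' hash, so different modules (initialisation, fold assignment, noise,
#' permutation nulls) never consume the same stream even when a user picks
#' adjacent seeds for related operations.
#'
#' @param seed integer user seed.
#' @param tag short string naming the consumer.
#' @return integer seed in [0, 2^31 - 2].
#' @keywords internal
.substream <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 8191) %% 2147483647)
}
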