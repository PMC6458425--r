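# Deterministic random-number substreams.
#
# Every stochastic stage of the package derives its own seed by stable
# hashing of (master seed, stage name), so that e.g. the exposure and outcome
# samples of a two-sample simulation use disjoint noise streams, and adding
# draws to one stage never perturbs another.  All arithmetic stays well below
# 2^53 so the hash is exact in doubles, and the result is a valid 32-bit
# integer seed.

#' Derive a stage-specific seed from a master seed
#'
#' @param seed master seed (integer-valued scalar).
#' @param stage character scalar naming the stage, e.g. `"outcome_noise"`.
#' @return an integer seed, deterministic in `(seed, stage)`.
#' @examples
#' substream_seed(1, "exposure") != substream_seed(1, "outcome")
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage),
            length(stage) == 1L, nzchar(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 7919) %% 2147483647
  s <- (abs(as.numeric(seed)) %% 65521) * 32749
  as.integer((s + h) %% 2147483647)
}

# run set.seed for a named stage
seed_stage <- function(seed, stage) {
  set.seed(substream_seed(seed, stage))
  invisible(NULL)
}
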