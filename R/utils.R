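#' Derive a stage seed from a master seed
#'
#' One master seed deterministically yields independent per-stage seeds
#' (simulation, balancing, splitting, training, ...) so pipeline stages can
#' be re-run in isolation. The derivation is a fixed affine hash modulo
#' 2^31 - 1, so derived seeds always fit a 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param stage Stage name, one of `"simulate"`, `"balance"`, `"split"`,
#'   `"train"`, `"evaluate"`.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage = c("simulate", "balance", "split",
                                        "train", "evaluate")) {
  stage <- match.arg(stage)
  offset <- c(simulate = 1, balance = 2, split = 3, train = 4, evaluate = 5)
  s <- (abs(as.numeric(seed)) * 48271 + offset[[stage]] * 1000003) %% 2147483647
  as.integer(s)
}
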