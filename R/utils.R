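# Internal helpers: validation conditions and seed derivation.

# Validation failures get their own condition class so the command-line
# wrapper can map them to exit code 2 (vs 1 for runtime errors).
stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("markergp_validation", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-label random seed from a master seed
#'
#' Stable 32-bit string hash (polynomial, base 31) of the label, folded into
#' the master seed. Adding new labels to a study never shifts the random
#' substream of existing labels.
#'
#' @param master_seed Integer master seed.
#' @param label Character scalar (e.g. "HCT-116 ABCG2+").
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, label) {
  mod <- 2147483647
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% mod
  }
  as.integer((abs(as.numeric(master_seed)) + h) %% mod)
}
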