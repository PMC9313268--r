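# Internal helpers shared across modules.

# Raise a classed condition so callers can distinguish failure modes.
otc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "opticlear_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Half-up rounding (round(1.5) in base R is banker's rounding; region sizes
# must not depend on the parity of the integer part).
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate code with a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, runs `code`, and restores the caller's
#' RNG state afterwards, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Derive the per-image substream seed: fixed offsets so adding images does
# not perturb the draws of earlier images. Kept below 2^31 - 1.
image_substream_seed <- function(seed, image_index) {
  (as.numeric(seed) + 10007 * as.numeric(image_index)) %% 2147483647
}
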