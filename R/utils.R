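# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: one master seed drives every stochastic
# stage, each with its own stream. Kept strictly below 2^31 - 1.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 1000003L + 1) * 1009 + offset) %% 2147483629L
}

# Validation conditions carry a distinct class so callers can discriminate
# failure modes programmatically.
abort_validation <- function(message, class) {
  stop(structure(
    class = c(class, "pulpdx_validation_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Half-up rounding to whole percent, the display convention of the
# human-readable report (base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
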