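# Internal helpers: argument checks and seed-substream derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

N_NOTES <- 12L
N_ITIS <- 11L

stop_taptrans <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "taptrans_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

assert_itis <- function(x, arg = deparse(substitute(x)), n = N_ITIS) {
  if (!is.numeric(x) || length(x) != n) {
    stop_taptrans(
      sprintf("`%s` must be a numeric ITI vector of length %d, got length %d",
              arg, n, length(x)),
      "taptrans_validation_error"
    )
  }
  if (any(!is.finite(x))) {
    stop_taptrans(sprintf("`%s` contains non-finite values", arg),
                  "taptrans_validation_error")
  }
  invisible(as.numeric(x))
}

assert_scalar_number <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_taptrans(
      sprintf("`%s` must be a single finite number in [%s, %s]", arg,
              format(lower), format(upper)),
      "taptrans_validation_error"
    )
  }
  invisible(as.numeric(x))
}

CONDITIONS <- c("LearnFromPerformance", "LearnFromDemonstration")

condition_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), CONDITIONS)
  if (length(bad) > 0) {
    stop_taptrans(
      sprintf("unknown condition label(s): %s (expected %s)",
              paste(bad, collapse = ", "), paste(CONDITIONS, collapse = ", ")),
      "taptrans_validation_error"
    )
  }
  # LearnFromPerformance is the reference level so that model intercepts are
  # interpretable as that condition's bias.
  factor(as.character(x), levels = CONDITIONS)
}

#' Derive a reproducible sub-seed for a named random stream
#'
#' All randomness in the simulator is governed by one `rng_seed`; independent
#' components (seed pool, each participant, covariates) draw from substreams
#' whose seeds are derived deterministically from the global seed and a string
#' label via a simple multiplicative hash. The result is always a valid
#' 32-bit seed.
#'
#' @param rng_seed integer master seed.
#' @param label character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(rng_seed, label) {
  assert_scalar_number(rng_seed, "rng_seed")
  h <- 0
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 131 + k) %% 2147483629
  }
  as.integer((abs(rng_seed) * 48271 + h * 30269 + 17) %% 2147483629)
}
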