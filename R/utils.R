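# Internal helpers shared across modules.

#' Derive an independent stream seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own seeded stream so
#' that adding or reordering a stage never perturbs another stage's draws.
#' The derivation is a small integer hash of the master seed and a stream
#' label, kept strictly below 2^31 so it is a valid R seed on all platforms.
#'
#' @param seed master integer seed.
#' @param stream character label of the stream (e.g. `"probes"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Single-value numeric validation with a readable error.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}
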