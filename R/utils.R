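# Internal helpers shared across modules.

# Deterministic substream seed derived from a root seed and a stage name.
# Adding a new stage never perturbs the draws of existing stages because each
# stage re-seeds from its own named substream. Kept well below 2^31.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(as.numeric(seed)) %% 100000) * 20011 + h * 13 + 17)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}

# wrap a value into [0, 1)
wrap_unit <- function(x) x - floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
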