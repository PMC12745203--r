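# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_config <- function(...) {
  stop(structure(class = c("gwx_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
stop_format <- function(...) {
  stop(structure(class = c("gwx_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Derive a stream-specific seed from a base seed; keeps results below 2^31
# so the value is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset) %% 2147483629)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prop <- function(x, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
}
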