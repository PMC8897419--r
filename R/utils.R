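# Internal condition helpers: classed errors so the CLI can map them to
# exit codes (usage = 2, data = 3, numerical = 4).

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("domgblup_usage_error", "domgblup_error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("domgblup_data_error", "domgblup_error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("domgblup_numerical_error", "domgblup_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific RNG seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range so they are valid
#' arguments to [set.seed()].
#'
#' @param seed master integer seed.
#' @param stream non-negative integer identifying the consumer.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647L)
}
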