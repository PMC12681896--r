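# Classed conditions so callers (and tests) can distinguish malformed input
# from genuinely insufficient data.

format_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("%s (line %d)", msg, as.integer(line))
  stop(errorCondition(msg, class = c("clonalpair_format_error", "clonalpair_error")))
}

validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("clonalpair_validation_error", "clonalpair_error")))
}

insufficient_data_error <- function(msg) {
  stop(errorCondition(msg, class = c("clonalpair_insufficient_data", "clonalpair_error")))
}

undefined_metric_error <- function(msg) {
  stop(errorCondition(msg, class = c("clonalpair_undefined_metric", "clonalpair_error")))
}
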