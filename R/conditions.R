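# Condition helpers: classed errors so callers (and the CLI) can map
# failures to exit codes -- usage (bad arguments), data (bad input files),
# numeric (optimisation failures).

abortUsage <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("slidenet_usage_error", "slidenet_error")))
}

abortData <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("slidenet_data_error", "slidenet_error")))
}

abortNumeric <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("slidenet_numeric_error", "slidenet_error")))
}

stageMessage <- function(stage, ...) {
  message(sprintf("[slidenet:%s] %s", stage, paste0(...)))
}
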