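# Condition classes used across the package so callers (and the command
# line wrappers) can distinguish contract violations from numerical
# failures: validation -> exit 2, numerical -> exit 3.

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("alkdiet_validation_error",
                                     "alkdiet_error", "error")))
}

stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("alkdiet_schema_error",
                                     "alkdiet_validation_error",
                                     "alkdiet_error", "error")))
}

stop_numerical <- function(msg, data = NULL) {
  stop(errorCondition(msg, data = data,
                      class = c("alkdiet_numerical_error",
                                "alkdiet_error", "error")))
}
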