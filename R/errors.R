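# Typed conditions used across the package. Exit-code mapping in run_cli()
# relies on these classes: validation -> 2, infeasibility -> 3, numerical -> 4.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("enzalloc_validation_error", "enzalloc_error")))
}

stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("enzalloc_infeasibility_error", "enzalloc_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("enzalloc_numerical_error", "enzalloc_error")))
}
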