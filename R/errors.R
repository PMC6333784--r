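# Structured conditions so callers (and the command-line wrapper) can tell
# bad input (exit 2) from numerical failure (exit 1).

ak_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "amylokin_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ak_validation_error <- function(msg) ak_stop(msg, "amylokin_validation_error")

ak_numeric_error <- function(msg) ak_stop(msg, "amylokin_numeric_error")
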