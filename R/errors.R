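# Classed conditions so callers (and the CLI) can map failure kinds to exit
# codes: usage/parameter errors, data-format errors, numerical degeneracies.

mp_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mpdfir_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_usage <- function(msg) mp_stop(msg, "mpdfir_usage_error")
stop_data <- function(msg) mp_stop(msg, "mpdfir_data_error")
stop_degenerate <- function(msg) mp_stop(msg, "mpdfir_degenerate_error")
stop_param <- function(msg) mp_stop(msg, "mpdfir_param_error")
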