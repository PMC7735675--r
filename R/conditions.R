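# Classed conditions so callers (and tests) can discriminate failure modes
# without matching message text.

tk_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "trimkit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

tk_warn <- function(class, message) {
  warning(structure(
    class = c(class, "trimkit_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}
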