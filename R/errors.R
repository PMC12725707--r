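# Typed condition helpers: every recoverable failure carries a subclass
# "xq_<what>" so callers (and the CLI) can branch without string-matching.

stop_xq <- function(what, message) {
  stop(structure(
    class = c(paste0("xq_", what), "xq_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
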