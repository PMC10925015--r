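# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., cdrnet_parse_error = ...).

cdr_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("cdrnet_", class), "cdrnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
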