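# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish configuration, parse and I/O failures.

abort_pulcall <- function(msg, class) {
  stop(structure(
    class = c(class, "pulcall_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(msg) abort_pulcall(msg, "pulcall_config_error")
abort_parse  <- function(msg) abort_pulcall(msg, "pulcall_parse_error")
abort_io     <- function(msg) abort_pulcall(msg, "pulcall_io_error")
abort_lookup <- function(msg) abort_pulcall(msg, "pulcall_lookup_error")
abort_type   <- function(msg) abort_pulcall(msg, "pulcall_type_error")
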