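# Classed conditions so callers (and the CLI) can map failures to exit
# codes: usage errors -> 1, data/format errors -> 2, numerical errors -> 3.

stop_usage <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "eem_usage_error")
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "eem_format_error")
}

stop_numeric <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "eem_numeric_error")
}
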