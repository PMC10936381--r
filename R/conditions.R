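# Classed conditions so callers (and the CLI) can map failures to exit codes.

netenrich_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "netenrich_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) netenrich_stop("netenrich_validation_error", msg, ...)
stop_format     <- function(msg, ...) netenrich_stop("netenrich_format_error", msg, ...)
stop_io         <- function(msg, ...) netenrich_stop("netenrich_io_error", msg, ...)
stop_generation <- function(msg, ...) netenrich_stop("netenrich_generation_error", msg, ...)
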