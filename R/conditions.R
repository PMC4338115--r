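# Condition helpers: every user-facing error carries a class so the CLI can
# map failures onto distinct exit codes.

stop_stagecif <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "stagecif_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_usage <- function(message) stop_stagecif(message, "stagecif_usage_error")
stop_parse <- function(message) stop_stagecif(message, "stagecif_parse_error")
stop_validation <- function(message) stop_stagecif(message, "stagecif_validation_error")
stop_estimation <- function(message) stop_stagecif(message, "stagecif_estimation_error")
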