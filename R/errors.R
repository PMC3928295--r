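## Classed conditions so callers (and the CLI) can map failures to categories.

fragopt_stop <- function(message, class, call. = FALSE) {
  stop(structure(class = c(class, "fragopt_error", "error", "condition"),
                 list(message = message, call = if (call.) sys.call(-1))))
}

abort_config   <- function(msg) fragopt_stop(msg, "fragopt_config_error")
abort_parse    <- function(msg) fragopt_stop(msg, "fragopt_parse_error")
abort_backend  <- function(msg) fragopt_stop(msg, "fragopt_backend_error")
abort_partition <- function(msg) fragopt_stop(msg, "fragopt_partition_error")
abort_index    <- function(msg) fragopt_stop(msg, "fragopt_index_error")
abort_argument <- function(msg) fragopt_stop(msg, "fragopt_argument_error")
abort_singularity <- function(msg) fragopt_stop(msg, "fragopt_singularity_error")
abort_polarization <- function(msg) fragopt_stop(msg, "fragopt_polarization_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
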