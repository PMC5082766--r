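# Classed error conditions used throughout the package so callers (and tests)
# can distinguish user error from pipeline failure.

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "adipoage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_config  <- function(msg, field = NULL) stop_with("adipoage_config_error", msg, field = field)
stop_domain  <- function(msg, ...) stop_with("adipoage_domain_error", msg, ...)
stop_input   <- function(msg, ...) stop_with("adipoage_input_error", msg, ...)
stop_support <- function(msg, ...) stop_with("adipoage_support_error", msg, ...)
stop_pipeline <- function(msg, ...) stop_with("adipoage_pipeline_error", msg, ...)
stop_missing <- function(msg, ...) stop_with("adipoage_missing_data_error", msg, ...)
stop_collinear <- function(msg, ...) stop_with("adipoage_collinearity_error", msg, ...)
stop_degenerate <- function(msg, ...) stop_with("adipoage_degenerate_error", msg, ...)
stop_summary <- function(msg, ...) stop_with("adipoage_summary_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
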