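clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

# round normalized coordinates to the precision stored in document sidecars
round_coord <- function(x) round(x, 6L)

stop_input <- function(msg, ...) abort(msg, class = "drawerseg_input_error", ...)
stop_format <- function(msg, ...) abort(msg, class = "drawerseg_format_error", ...)
stop_param <- function(msg, ...) abort(msg, class = "drawerseg_parameter_error", ...)
stop_geometry <- function(msg, ...) abort(msg, class = "drawerseg_geometry_error", ...)
stop_corrupt <- function(msg, ...) abort(msg, class = "drawerseg_document_corrupt", ...)
stop_refusal <- function(msg, ...) abort(msg, class = "drawerseg_refusal_error", ...)
stop_schema <- function(msg, ...) abort(msg, class = "drawerseg_schema_error", ...)
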