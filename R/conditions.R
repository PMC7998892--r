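# Classed conditions so callers can distinguish failure modes programmatically.

stop_naagif <- function(msg, class) {
  stop(structure(
    class = c(class, "naagif_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

err_invalid <- function(msg) stop_naagif(msg, "naagif_invalid_parameter")
err_range <- function(msg) stop_naagif(msg, "naagif_range_error")
err_structural <- function(msg) stop_naagif(msg, "naagif_structural_error")
err_numerical <- function(msg) stop_naagif(msg, "naagif_numerical_failure")
err_parse <- function(msg) stop_naagif(msg, "naagif_parse_error")
err_config <- function(msg) stop_naagif(msg, "naagif_config_error")
err_degenerate <- function(msg) stop_naagif(msg, "naagif_degenerate_spectrum")
err_fit <- function(msg) stop_naagif(msg, "naagif_fit_failure")
err_insufficient <- function(msg) stop_naagif(msg, "naagif_insufficient_data")
err_io <- function(msg) stop_naagif(msg, "naagif_io_error")
err_usage <- function(msg) stop_naagif(msg, "naagif_usage_error")

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
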