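#' @keywords internal
"_PACKAGE"

# Interaction class labels, in the fixed reporting order used everywhere.
INTERACTION_CLASSES <- c("SG+D", "D", "SG", "Other")

#' Round half away from zero
#'
#' Reporting convention for metrics (2 decimals) and percentages (1 decimal):
#' ties round away from zero, unlike base R's round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an epsilon-free trunc construction
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

stop_input <- function(...) {
  stop(structure(
    class = c("screentalk_input_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("screentalk_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
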