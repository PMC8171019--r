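# Shared helpers: rounding, condition classes, small numerics.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the Sturges bin-count rule here
#' needs the grade-school convention (0.5 -> 1, -0.5 -> -1).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Stage-tagged conditions so the command-line driver can map failures to
# exit codes (2 io, 3 preprocessing, 4 clustering, 5 selection).
stop_io <- function(message, ...) {
  abort(message, class = c("cafw_io_error", "cafw_error"), ...)
}

stop_preprocess <- function(message, ...) {
  abort(message, class = c("cafw_preprocess_error", "cafw_error"), ...)
}

stop_cluster <- function(message, ...) {
  abort(message, class = c("cafw_cluster_error", "cafw_error"), ...)
}

stop_selection <- function(message, ...) {
  abort(message, class = c("cafw_selection_error", "cafw_error"), ...)
}

# Population standard deviation (divisor n, not n - 1), columnwise.
col_sd_pop <- function(m) {
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  sqrt(pmax(v, 0))
}
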