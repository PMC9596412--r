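#' Signal a classed pipeline error
#'
#' All user-facing errors in the package carry a stable machine-readable
#' code (e.g. "oov-token", "unsorted-transcript") so callers and tests can
#' match on the condition class rather than the message text.
#'
#' @param code Short kebab-case error code.
#' @param msg Human-readable message.
#' @keywords internal
stop_surpsal <- function(code, msg) {
  cls <- paste0("surpsal_error_", gsub("-", "_", code, fixed = TRUE))
  stop(structure(
    class = c(cls, "surpsal_error", "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), call = sys.call(-1))
  ))
}

#' Z-score a vector over a logical mask
#'
#' Standardizes using mean and sd computed on the masked-in points only;
#' masked-out points are transformed with the same location/scale so the
#' full-length series stays aligned to the scan grid.
#'
#' @param x Numeric vector.
#' @param mask Logical vector, same length; TRUE = point enters the fit.
#' @keywords internal
zscore_masked <- function(x, mask = rep(TRUE, length(x))) {
  m <- mean(x[mask])
  s <- stats::sd(x[mask])
  if (!is.finite(s) || s == 0) {
    stop_surpsal("degenerate-column", "cannot z-score a constant series")
  }
  (x - m) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
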