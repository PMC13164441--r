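`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nccthist <- function(...) stop(..., call. = FALSE)

assert_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_nccthist(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_nccthist(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

# Piecewise-linear interpolation with flat extrapolation outside the knots.
interp_flat <- function(x, xp, yp) {
  stats::approx(xp, yp, xout = pmin(pmax(x, min(xp)), max(xp)), ties = "ordered")$y
}
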