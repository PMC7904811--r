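# internal helpers shared across modules

#' Geometric mean of strictly positive values
#'
#' Values that are zero or negative are dropped before averaging; an empty
#' set after dropping yields `NA`.
#' @param x numeric vector
#' @return the geometric mean of the positive entries of `x`
#' @keywords internal
#' @noRd
geomean <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0L) return(NA_real_)
  exp(mean(log(x)))
}

# evaluate `code` under a fixed RNG state without disturbing the caller's;
# seed = NULL means "use the current RNG stream"
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stop_mirplat <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mirplat("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stop_mirplat("'%s' must be positive (got %g)", name, x)
  invisible(x)
}
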