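# Small numerical helpers shared across modules.

# round-half-away-from-zero; base round() is banker's rounding
.roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Trapezoidal area under a curve
#'
#' Integrates `y` over `x` by the trapezoidal rule on the actual grid points.
#' This is the AUC summary used to collapse a metric-versus-density (or
#' LCC-versus-removal-fraction) curve into one comparable number.
#'
#' @param x numeric vector of strictly increasing abscissae (length >= 2).
#' @param y numeric vector of ordinates, same length as `x`.
#' @return A single numeric area.
#' @examples
#' aucTrapezoid(c(0, 1), c(1, 1))   # 1
#' @export
aucTrapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, !is.unsorted(x, strictly = TRUE))
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# evaluate expr under a temporary seed (restoring the RNG state afterwards);
# seed = NULL means "use the current RNG stream"
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# substream seeds derived from one user seed so that the order in which groups
# (or simulations) are generated cannot change any single group's draw;
# kept below .Machine$integer.max
.subSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(index)) %% 2147483647)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x), call. = FALSE)
  invisible(x)
}
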