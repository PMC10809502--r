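# Internal helpers: unit conversion, rounding, noise.

# 1 uL = 1e-3 cm^3
ul_to_cm3 <- function(x) x * 1e-3

#' Round half away from zero
#'
#' Rounding used when comparing derived quantities with values printed to a
#' fixed number of decimals (e.g. efflux ratios reported to 1 d.p.). Base R's
#' `round()` rounds half to even; printed assay tables conventionally round
#' half away from zero, so 4.35 becomes 4.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(4.35, 1) # 4.4, where round(4.35, 1) gives 4.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Mean-one multiplicative lognormal errors with coefficient of variation cv.
# sdlog^2 = log(1 + cv^2); meanlog = -sdlog^2/2 so E[eps] = 1.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
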