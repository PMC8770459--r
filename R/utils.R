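# Internal numeric helpers shared across modules.

# Accept either a WavelengthGrid or a plain numeric vector of wavelengths.
as_wl <- function(grid) {
  if (is(grid, "WavelengthGrid")) return(wavelengths(grid))
  if (is.numeric(grid) && length(grid) >= 2L) return(as.numeric(grid))
  stop("'grid' must be a WavelengthGrid or a numeric wavelength vector")
}

# Trapezoid quadrature weights for an (ascending, possibly non-uniform) grid,
# so that sum(w * y) == integral of the linear interpolant of y.
trapzWeights <- function(x) {
  n <- length(x)
  d <- diff(x)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  w
}

trapz <- function(x, y) sum(trapzWeights(x) * y)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate code under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed uses (and advances) the current stream.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
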