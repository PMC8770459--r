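#' @include AllClasses.R
NULL

# Unnormalized A1 visual-pigment absorbance (alpha + beta band) evaluated at
# arbitrary wavelengths; the Govardovskii-type lambda-max-parameterized
# nomogram used throughout.
a1_absorbance <- function(lambdaMax, wl) {
  x <- lambdaMax / wl
  a <- 0.8795 + 0.0459 * exp(-(lambdaMax - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) + 0.674)
  lmb <- 189 + 0.315 * lambdaMax
  b <- -40.5 + 0.195 * lambdaMax
  beta <- 0.26 * exp(-((wl - lmb) / b)^2)
  alpha + beta
}

#' A1 visual-pigment template sensitivity
#'
#' Builds a photoreceptor spectral sensitivity from the standard A1
#' (retinal) chromophore nomogram: an alpha band parameterized by the peak
#' wavelength plus the ultraviolet beta band, summed and renormalized to a
#' peak of 1.
#'
#' @param lambdaMax peak wavelength in nm, within the template's 330--700 nm
#'   validity range.
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A [ReceptorSensitivity-class] with mechanism `"template"`.
#' @references Govardovskii et al. (2000) Visual Neuroscience 17, 509-528
#'   (the A1 nomogram coefficients).
#' @export
a1Template <- function(lambdaMax, grid = defaultGrid()) {
  if (lambdaMax < 330 || lambdaMax > 700)
    stop("lambdaMax must lie in the template validity range 330-700 nm")
  wl <- as_wl(grid)
  v <- a1_absorbance(lambdaMax, wl)
  new("ReceptorSensitivity", lambdaMax = lambdaMax,
      curve = Spectrum(v / max(v), wl, kind = "sensitivity",
                       label = sprintf("A1_%g", lambdaMax)),
      mechanism = "template", filterCut = NA_real_, filterSlope = NA_real_)
}

#' Logistic long-pass filter transmission
#'
#' T(lambda) = 1 / (1 + exp(-slope * (lambda - cut))): transmission 0.5 at
#' the cut wavelength, rising toward 1 at long wavelengths — the functional
#' form of a coloured screening pigment overlying a photoreceptor.
#'
#' @param cut midpoint wavelength in nm.
#' @param slope steepness in nm^-1, > 0.
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A transmission-kind [Spectrum-class].
#' @export
longpassFilter <- function(cut, slope, grid = defaultGrid()) {
  stopifnot(slope > 0)
  wl <- as_wl(grid)
  Spectrum(stats::plogis(slope * (wl - cut)), wl, kind = "transmission",
           label = sprintf("longpass_%g", cut))
}

#' Red-shift a receptor with a long-pass screening filter
#'
#' Emulates filtering-pigment red shifts: the fixed A1 template at
#' `baseLambdaMax` is multiplied by a logistic long-pass filter whose cut
#' wavelength is solved by bisection so the product peaks at
#' `targetLambdaMax`, then renormalized to peak 1. The peak is located on a
#' 0.1 nm refined grid to avoid quantization plateaus. The resulting curve
#' is narrower than an opsin-shifted template of equal peak, and absolute
#' sensitivity loss from the filter is deliberately not modelled (the
#' discrimination model uses relative sensitivities).
#'
#' @param targetLambdaMax desired peak in nm, > `baseLambdaMax`.
#' @param baseLambdaMax peak of the underlying visual pigment (default 570
#'   nm, the longest known A1 pigment).
#' @param slope filter steepness in nm^-1 (default 0.1).
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A [ReceptorSensitivity-class] with mechanism `"filter-shifted"`
#'   and the solved cut recorded in its slots.
#' @export
filterShiftedReceptor <- function(targetLambdaMax, baseLambdaMax = 570,
                                  slope = 0.1, grid = defaultGrid()) {
  stopifnot(targetLambdaMax > baseLambdaMax, slope > 0)
  wl <- as_wl(grid)
  if (targetLambdaMax > max(wl))
    stop("target peak lies beyond the wavelength grid")
  fine <- seq(max(min(wl), baseLambdaMax - 80), max(wl), by = 0.1)
  base_fine <- a1_absorbance(baseLambdaMax, fine)
  peak_at <- function(cut) {
    fine[which.max(base_fine * stats::plogis(slope * (fine - cut)))]
  }
  lo <- baseLambdaMax - 50
  hi <- baseLambdaMax + 300
  if (peak_at(lo) > targetLambdaMax || peak_at(hi) < targetLambdaMax)
    stop(sprintf("solver error: peak %g nm not reachable for slope %g",
                 targetLambdaMax, slope))
  while (hi - lo > 0.05) {
    mid <- (lo + hi) / 2
    if (peak_at(mid) < targetLambdaMax) lo <- mid else hi <- mid
  }
  cut <- (lo + hi) / 2
  if (abs(peak_at(cut) - targetLambdaMax) > 1)
    stop("solver error: bisection failed to place the peak within 1 nm")
  v <- a1_absorbance(baseLambdaMax, wl) * stats::plogis(slope * (wl - cut))
  new("ReceptorSensitivity", lambdaMax = targetLambdaMax,
      curve = Spectrum(v / max(v), wl, kind = "sensitivity",
                       label = sprintf("filter_%g", targetLambdaMax)),
      mechanism = "filter-shifted", filterCut = cut, filterSlope = slope)
}

#' Red-shift a receptor by moving the template peak
#'
#' Emulates opsin-sequence shifts: the A1 template is generated directly at
#' the requested peak, giving a much broader curve than the filter-shifted
#' equivalent.
#'
#' @param lambdaMax peak wavelength in nm.
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A [ReceptorSensitivity-class] with mechanism `"opsin-shifted"`.
#' @export
opsinShiftedReceptor <- function(lambdaMax, grid = defaultGrid()) {
  r <- a1Template(lambdaMax, grid)
  new("ReceptorSensitivity", lambdaMax = r@lambdaMax, curve = r@curve,
      mechanism = "opsin-shifted", filterCut = NA_real_,
      filterSlope = NA_real_)
}

#' Full width at half maximum of a sensitivity curve
#'
#' Width between the outermost 0.5 crossings of the peak-normalized curve,
#' located by linear interpolation on a 0.1 nm refinement.
#'
#' @param receptor a [ReceptorSensitivity-class] (or sensitivity
#'   [Spectrum-class]).
#' @return Width in nm.
#' @export
fwhm <- function(receptor) {
  s <- if (is(receptor, "ReceptorSensitivity")) receptor@curve else receptor
  wl <- s@wl
  fine <- seq(min(wl), max(wl), by = 0.1)
  v <- stats::approx(wl, s@values / max(s@values), xout = fine)$y
  above <- which(v >= 0.5)
  cross <- function(i, j) {
    # linear interpolation of the 0.5 crossing between fine[i] and fine[j]
    fine[i] + (0.5 - v[i]) * (fine[j] - fine[i]) / (v[j] - v[i])
  }
  left <- if (above[1L] == 1L) fine[1L] else
    cross(above[1L] - 1L, above[1L])
  n <- length(v)
  right <- if (above[length(above)] == n) fine[n] else
    cross(above[length(above)] + 1L, above[length(above)])
  right - left
}
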