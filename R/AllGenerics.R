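#' @include utils.R
NULL

#' Wavelength vector of a grid or spectral object
#'
#' @param x a `WavelengthGrid`, `Spectrum`, `Illuminant` or
#'   `ReceptorSensitivity` object.
#' @return Numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Spectral values of an object
#'
#' @param x a `Spectrum`, `Illuminant` or `ReceptorSensitivity`.
#' @return Numeric vector of per-wavelength values (reflectance, irradiance,
#'   sensitivity or transmission depending on the object's kind).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' Kind of a spectral curve
#'
#' One of `"reflectance"`, `"irradiance-energy"`, `"irradiance-photon"`,
#' `"sensitivity"`, `"transmission"`.
#'
#' @param x a `Spectrum` or `Illuminant`.
#' @return Character scalar.
#' @export
setGeneric("specKind", function(x) standardGeneric("specKind"))

#' Sample label of a spectral object
#'
#' @param x a `Spectrum`, `Illuminant`, `ReceptorSensitivity` or
#'   `VisualSystem`.
#' @return Character scalar.
#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))

#' Nominal peak wavelength of a receptor
#'
#' @param x a `ReceptorSensitivity`.
#' @return Peak sensitivity wavelength (lambda-max) in nm.
#' @export
setGeneric("lambdaMax", function(x) standardGeneric("lambdaMax"))

#' Generating mechanism of a receptor sensitivity
#'
#' @param x a `ReceptorSensitivity`.
#' @return `"template"`, `"filter-shifted"` or `"opsin-shifted"`.
#' @export
setGeneric("mechanism", function(x) standardGeneric("mechanism"))

#' Receptor classes of a visual system
#'
#' @param x a `VisualSystem`.
#' @return Named list of `ReceptorSensitivity` objects in ascending
#'   lambda-max order.
#' @export
setGeneric("receptors", function(x) standardGeneric("receptors"))

#' Relative receptor densities of a visual system
#'
#' @param x a `VisualSystem`.
#' @return Named numeric vector of relative densities, one per receptor
#'   class.
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' Noise mode of a visual system
#'
#' @param x a `VisualSystem`.
#' @return `"neural"` or `"quantum"`.
#' @export
setGeneric("noiseMode", function(x) standardGeneric("noiseMode"))

#' Chromatic contrast in just-noticeable differences
#'
#' @param x a `ContrastResult`.
#' @return Nonnegative numeric scalar (JND).
#' @export
setGeneric("deltaS", function(x) standardGeneric("deltaS"))

#' Per-receptor log-signal differences of a contrast result
#'
#' @param x a `ContrastResult`.
#' @return Named numeric vector of Fechner-signal differences, one per
#'   receptor class.
#' @export
setGeneric("deltaF", function(x) standardGeneric("deltaF"))
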