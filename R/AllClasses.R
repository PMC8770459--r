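#' @include AllGenerics.R
NULL

.SPECTRUM_KINDS <- c("reflectance", "irradiance-energy", "irradiance-photon",
                     "sensitivity", "transmission")

#' WavelengthGrid: a regular wavelength sampling
#'
#' Defines the common wavelength axis used by all spectral objects. The
#' default grid covers 300--800 nm inclusive at 1 nm (501 points), the range
#' over which insect photoreceptors and field spectrometry typically operate.
#'
#' @slot start first wavelength (nm).
#' @slot stop last wavelength (nm).
#' @slot step sampling interval (nm).
#' @export
setClass("WavelengthGrid",
  representation(start = "numeric", stop = "numeric", step = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@start < object@stop)) msg <- c(msg, "start must be < stop")
    if (!(object@step > 0)) msg <- c(msg, "step must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a wavelength grid
#'
#' @param start,stop,step grid definition in nm; defaults give the 300--800
#'   nm, 1 nm grid (501 points).
#' @return A [WavelengthGrid-class] object.
#' @examples
#' length(wavelengths(WavelengthGrid()))  # 501
#' @export
WavelengthGrid <- function(start = 300, stop = 800, step = 1) {
  new("WavelengthGrid", start = start, stop = stop, step = step)
}

#' Default 300--800 nm, 1 nm wavelength grid
#'
#' @return A [WavelengthGrid-class] object.
#' @export
defaultGrid <- function() WavelengthGrid()

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x) {
  seq(x@start, x@stop, by = x@step)
})

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %g-%g nm, step %g nm (%d points)\n",
              object@start, object@stop, object@step,
              length(wavelengths(object))))
})

#' Spectrum: a wavelength-indexed curve
#'
#' Holds one spectral curve on an explicit wavelength axis. The `kind` slot
#' records what the values mean (and hence their units): unitless reflectance
#' or transmission in 0--1, peak-normalized sensitivity, or irradiance on an
#' energy (W m-2 nm-1) or photon (photons s-1 m-2 nm-1) basis, either
#' absolute or relative.
#'
#' @slot wl wavelengths in nm, strictly ascending.
#' @slot values nonnegative finite values, same length as `wl`.
#' @slot kind one of `"reflectance"`, `"irradiance-energy"`,
#'   `"irradiance-photon"`, `"sensitivity"`, `"transmission"`.
#' @slot label sample identifier.
#' @export
setClass("Spectrum",
  representation(wl = "numeric", values = "numeric", kind = "character",
                 label = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@wl) != length(object@values))
      msg <- c(msg, "values and wl must have equal length")
    if (any(diff(object@wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly ascending")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    else if (any(object@values < 0))
      msg <- c(msg, "values must be nonnegative")
    if (length(object@kind) != 1L || !object@kind %in% .SPECTRUM_KINDS)
      msg <- c(msg, paste("kind must be one of:",
                          paste(.SPECTRUM_KINDS, collapse = ", ")))
    else if (object@kind %in% c("sensitivity", "transmission") &&
             length(object@values) && max(object@values) > 1 + 1e-9)
      msg <- c(msg, sprintf("%s values must not exceed 1", object@kind))
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Spectrum
#'
#' @param values numeric vector of spectral values.
#' @param grid a [WavelengthGrid-class] or numeric wavelength vector matching
#'   `values`.
#' @param kind curve kind, see [Spectrum-class].
#' @param label sample identifier.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(rep(0.5, 501), kind = "reflectance", label = "grey")
#' @export
Spectrum <- function(values, grid = defaultGrid(), kind = "reflectance",
                     label = "") {
  new("Spectrum", wl = as_wl(grid), values = as.numeric(values),
      kind = kind, label = label)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wl)

#' @rdname intensities
#' @export
setMethod("intensities", "Spectrum", function(x) x@values)

#' @rdname specKind
#' @export
setMethod("specKind", "Spectrum", function(x) x@kind)

#' @rdname specLabel
#' @export
setMethod("specLabel", "Spectrum", function(x) x@label)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s' (%s): %g-%g nm, %d points, range [%.4g, %.4g]\n",
              object@label, object@kind, min(object@wl), max(object@wl),
              length(object@wl), min(object@values), max(object@values)))
})

#' Illuminant: an irradiance spectrum with a scale convention
#'
#' Wraps an irradiance [Spectrum-class] and records whether its values are on
#' an absolute scale (required for photon shot-noise modelling, where actual
#' photon counts matter) or merely relative (sufficient for neural-noise
#' models, which are invariant to overall illuminant intensity).
#'
#' @slot spectrum an irradiance-kind `Spectrum`.
#' @slot scale `"absolute"` or `"relative"`.
#' @export
setClass("Illuminant",
  representation(spectrum = "Spectrum", scale = "character"),
  validity = function(object) {
    msg <- NULL
    if (!grepl("^irradiance-", object@spectrum@kind))
      msg <- c(msg, "illuminant spectrum must have an irradiance kind")
    if (length(object@scale) != 1L ||
        !object@scale %in% c("absolute", "relative"))
      msg <- c(msg, "scale must be 'absolute' or 'relative'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an Illuminant
#'
#' @param spectrum an irradiance-kind [Spectrum-class].
#' @param scale `"absolute"` or `"relative"`.
#' @return An [Illuminant-class] object.
#' @export
Illuminant <- function(spectrum, scale = "relative") {
  new("Illuminant", spectrum = spectrum, scale = scale)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Illuminant", function(x) x@spectrum@wl)

#' @rdname intensities
#' @export
setMethod("intensities", "Illuminant", function(x) x@spectrum@values)

#' @rdname specKind
#' @export
setMethod("specKind", "Illuminant", function(x) x@spectrum@kind)

#' @rdname specLabel
#' @export
setMethod("specLabel", "Illuminant", function(x) x@spectrum@label)

setMethod("show", "Illuminant", function(object) {
  cat(sprintf("Illuminant '%s' (%s, %s scale)\n", object@spectrum@label,
              object@spectrum@kind, object@scale))
})

#' ReceptorSensitivity: a normalized photoreceptor sensitivity curve
#'
#' A spectral sensitivity curve, peak-normalized to 1, together with its
#' nominal peak wavelength and the mechanism that produced it: the bare A1
#' visual-pigment template, a long-pass screening-pigment filter applied to a
#' fixed-template receptor (`"filter-shifted"`), or the template moved bodily
#' to a longer peak (`"opsin-shifted"`).
#'
#' @slot lambdaMax nominal peak wavelength in nm.
#' @slot curve a sensitivity-kind [Spectrum-class], max 1.
#' @slot mechanism `"template"`, `"filter-shifted"` or `"opsin-shifted"`.
#' @slot filterCut long-pass filter midpoint in nm (`NA` unless
#'   filter-shifted).
#' @slot filterSlope filter steepness in nm^-1 (`NA` unless filter-shifted).
#' @export
setClass("ReceptorSensitivity",
  representation(lambdaMax = "numeric", curve = "Spectrum",
                 mechanism = "character", filterCut = "numeric",
                 filterSlope = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@mechanism %in% c("template", "filter-shifted",
                                 "opsin-shifted"))
      msg <- c(msg, "unknown mechanism")
    if (object@curve@kind != "sensitivity")
      msg <- c(msg, "curve must be of kind 'sensitivity'")
    v <- object@curve@values
    if (abs(max(v) - 1) > 1e-9)
      msg <- c(msg, "curve must be peak-normalized to 1")
    peak <- object@curve@wl[which.max(v)]
    if (abs(peak - object@lambdaMax) > 1 + 1e-9)
      msg <- c(msg, sprintf(
        "curve peaks at %g nm, more than 1 nm from nominal lambda-max %g nm",
        peak, object@lambdaMax))
    if (is.null(msg)) TRUE else msg
  })

#' @rdname lambdaMax
#' @export
setMethod("lambdaMax", "ReceptorSensitivity", function(x) x@lambdaMax)

#' @rdname mechanism
#' @export
setMethod("mechanism", "ReceptorSensitivity", function(x) x@mechanism)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "ReceptorSensitivity", function(x) x@curve@wl)

#' @rdname intensities
#' @export
setMethod("intensities", "ReceptorSensitivity", function(x) x@curve@values)

setMethod("show", "ReceptorSensitivity", function(object) {
  extra <- if (object@mechanism == "filter-shifted")
    sprintf(" (cut %.1f nm, slope %.3g /nm)", object@filterCut,
            object@filterSlope) else ""
  cat(sprintf("ReceptorSensitivity: lambda-max %g nm, %s%s\n",
              object@lambdaMax, object@mechanism, extra))
})

#' VisualSystem: receptor classes, densities and noise
#'
#' An ordered set of 2--4 receptor classes (ascending peak wavelength) with
#' relative densities, a shared single-receptor noise parameter `nu`, and a
#' noise mode: `"neural"` (Weber-fraction-limited) or `"quantum"` (neural
#' plus photon shot noise, for dim light).
#'
#' @slot receptors named list of [ReceptorSensitivity-class] objects.
#' @slot densities named numeric vector of relative densities.
#' @slot nu single-receptor noise (unitless, > 0).
#' @slot noiseMode `"neural"` or `"quantum"`.
#' @slot label system name, e.g. `"USML"`.
#' @export
setClass("VisualSystem",
  representation(receptors = "list", densities = "numeric", nu = "numeric",
                 noiseMode = "character", label = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@receptors)
    if (n < 2L || n > 4L)
      msg <- c(msg, "a visual system needs 2-4 receptor classes")
    if (!all(vapply(object@receptors, is, logical(1),
                    class2 = "ReceptorSensitivity")))
      msg <- c(msg, "receptors must be ReceptorSensitivity objects")
    else {
      lm <- vapply(object@receptors, lambdaMax, numeric(1))
      if (any(diff(lm) <= 0))
        msg <- c(msg, "receptor lambda-max must be strictly increasing")
    }
    if (length(object@densities) != n || any(object@densities <= 0))
      msg <- c(msg, "densities must be positive, one per receptor class")
    if (!isTRUE(object@nu > 0)) msg <- c(msg, "nu must be > 0")
    if (!object@noiseMode %in% c("neural", "quantum"))
      msg <- c(msg, "noiseMode must be 'neural' or 'quantum'")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VisualSystem
#'
#' @param receptors named list of [ReceptorSensitivity-class] objects in
#'   ascending lambda-max order; names are the receptor class names
#'   (e.g. UVS, SWS, MWS, LWS).
#' @param densities named numeric vector of relative densities matching
#'   `receptors`.
#' @param nu single-receptor noise; see [deriveNu()].
#' @param noiseMode `"neural"` or `"quantum"`.
#' @param label system name.
#' @return A [VisualSystem-class] object.
#' @seealso [buildNamedSystem()] for the standard named systems.
#' @export
VisualSystem <- function(receptors, densities, nu, noiseMode = "neural",
                         label = "") {
  densities <- densities[names(receptors)]
  new("VisualSystem", receptors = receptors, densities = densities,
      nu = nu, noiseMode = noiseMode, label = label)
}

#' @rdname receptors
#' @export
setMethod("receptors", "VisualSystem", function(x) x@receptors)

#' @rdname densities
#' @export
setMethod("densities", "VisualSystem", function(x) x@densities)

#' @rdname noiseMode
#' @export
setMethod("noiseMode", "VisualSystem", function(x) x@noiseMode)

#' @rdname specLabel
#' @export
setMethod("specLabel", "VisualSystem", function(x) x@label)

setMethod("show", "VisualSystem", function(object) {
  lm <- vapply(object@receptors, lambdaMax, numeric(1))
  cat(sprintf("VisualSystem '%s' (%s noise, nu = %.5f)\n", object@label,
              object@noiseMode, object@nu))
  cat(sprintf("  %s: lambda-max %g nm, density %.4f (%s)\n",
              names(object@receptors), lm, object@densities,
              vapply(object@receptors, mechanism, character(1))), sep = "")
})

#' ContrastResult: one spectrum pair's chromatic contrast
#'
#' Per-receptor Fechner log-signal differences, per-receptor noise, and the
#' scalar receptor-noise-limited contrast in just-noticeable differences.
#'
#' @slot pair the two stimulus labels.
#' @slot deltaF named per-class log-signal differences.
#' @slot noise named per-class noise values e_i.
#' @slot deltaS chromatic contrast (JND, >= 0).
#' @export
setClass("ContrastResult",
  representation(pair = "character", deltaF = "numeric", noise = "numeric",
                 deltaS = "numeric"),
  validity = function(object) {
    if (object@deltaS < 0) "deltaS must be nonnegative" else TRUE
  })

#' @rdname deltaS
#' @export
setMethod("deltaS", "ContrastResult", function(x) x@deltaS)

#' @rdname deltaF
#' @export
setMethod("deltaF", "ContrastResult", function(x) x@deltaF)

#' Per-class noise of a contrast result
#'
#' @param x a `ContrastResult`.
#' @return Named numeric vector of per-receptor-class noise values.
#' @export
noiseValues <- function(x) {
  stopifnot(is(x, "ContrastResult"))
  x@noise
}

setMethod("show", "ContrastResult", function(object) {
  cat(sprintf("ContrastResult '%s' vs '%s': deltaS = %.4f JND\n",
              object@pair[1L], object@pair[2L], object@deltaS))
  df <- rbind(deltaF = object@deltaF, noise = object@noise)
  print(round(df, 4))
})
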