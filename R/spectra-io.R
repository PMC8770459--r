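#' @include AllClasses.R
NULL

# Planck constant (J s) and speed of light (m s-1), 2019 SI exact values.
.PLANCK <- 6.62607015e-34
.LIGHTSPEED <- 2.99792458e8

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; no extrapolation is performed. Resampling onto the
#' spectrum's own grid is the identity.
#'
#' @param x a [Spectrum-class].
#' @param grid target [WavelengthGrid-class] or numeric wavelength vector.
#' @return A [Spectrum-class] on the target grid.
#' @export
resampleSpectrum <- function(x, grid) {
  wl <- as_wl(grid)
  if (identical(wl, x@wl)) return(x)
  if (min(wl) < min(x@wl) || max(wl) > max(x@wl))
    stop(sprintf(
      "grid %g-%g nm outside data range %g-%g nm (no extrapolation)",
      min(wl), max(wl), min(x@wl), max(x@wl)))
  v <- stats::approx(x@wl, x@values, xout = wl)$y
  Spectrum(v, wl, kind = x@kind, label = x@label)
}

#' Read a wide-format table of spectra
#'
#' Reads a delimited text table (comma, tab or whitespace autodetected):
#' column 1 holds wavelengths in nm (ascending), each remaining column one
#' sample, with a header row of labels. Each sample is resampled to `grid`
#' by linear interpolation; negative values (spectrometer noise dipping
#' below the floor) are clamped to 0 with a warning.
#'
#' @param path file path.
#' @param grid target [WavelengthGrid-class] or wavelength vector; the data
#'   must cover its full range (no extrapolation).
#' @param kind curve kind to assign, default `"reflectance"`.
#' @return Named list of [Spectrum-class] objects.
#' @seealso [writeSpectraTable()] for the inverse.
#' @export
readSpectraTable <- function(path, grid = defaultGrid(),
                             kind = "reflectance") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("spectra table needs a wavelength column plus ",
                           "at least one sample column")
  wl <- as.numeric(tab[[1L]])
  if (anyNA(wl) || any(diff(wl) <= 0))
    stop("format error: wavelength column must be numeric and strictly ",
         "ascending")
  target <- as_wl(grid)
  if (min(target) < min(wl) || max(target) > max(wl))
    stop(sprintf(
      "range error: data cover %g-%g nm but grid requires %g-%g nm",
      min(wl), max(wl), min(target), max(target)))
  out <- lapply(names(tab)[-1L], function(lab) {
    v <- stats::approx(wl, as.numeric(tab[[lab]]), xout = target)$y
    if (any(v < 0)) {
      warning(sprintf("'%s': %d negative values clamped to 0", lab,
                      sum(v < 0)))
      v[v < 0] <- 0
    }
    Spectrum(v, target, kind = kind, label = lab)
  })
  names(out) <- names(tab)[-1L]
  out
}

#' Write spectra as a wide-format table
#'
#' @param spectra list of [Spectrum-class] objects on a common grid.
#' @param path output file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return Invisibly, `path`.
#' @export
writeSpectraTable <- function(spectra, path, sep = ",") {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]@wl
  for (s in spectra) stopifnot(identical(s@wl, wl))
  labs <- vapply(spectra, specLabel, character(1))
  if (any(labs == "")) labs[labs == ""] <- paste0("s", which(labs == ""))
  tab <- data.frame(wl = wl, check.names = FALSE)
  for (i in seq_along(spectra)) tab[[labs[i]]] <- spectra[[i]]@values
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Pointwise mean of spectra
#'
#' Used in particular for the mean-foliage adapting background of the
#' von Kries step.
#'
#' @param spectra nonempty list of [Spectrum-class] objects sharing one grid
#'   and kind.
#' @param label label for the result.
#' @return A [Spectrum-class].
#' @export
meanSpectrum <- function(spectra, label = "mean") {
  if (length(spectra) == 0L) stop("cannot average an empty list of spectra")
  wl <- spectra[[1L]]@wl
  kind <- spectra[[1L]]@kind
  for (s in spectra) {
    if (!identical(s@wl, wl)) stop("spectra must share one wavelength grid")
    if (s@kind != kind) stop("spectra must share one kind")
  }
  m <- rowMeans(vapply(spectra, intensities, numeric(length(wl))))
  Spectrum(m, wl, kind = kind, label = label)
}

#' Convert energy irradiance to photon flux
#'
#' Applies N(lambda) = E(lambda) * lambda / (h c), with the wavelength in
#' metres, turning W m-2 nm-1 into photons s-1 m-2 nm-1. Photon shot-noise
#' modelling needs absolute photon fluxes, so a relative input is only
#' accepted together with an explicit absolute scale factor.
#'
#' @param illum an energy-basis [Illuminant-class].
#' @param absoluteScale multiplicative factor converting a relative spectrum
#'   to absolute W m-2 nm-1; required when `illum` is relative.
#' @return An absolute photon-basis [Illuminant-class].
#' @export
toPhotonFlux <- function(illum, absoluteScale = NULL) {
  stopifnot(is(illum, "Illuminant"))
  if (specKind(illum) != "irradiance-energy")
    stop("input must be an energy-basis irradiance spectrum")
  E <- intensities(illum)
  if (illum@scale == "relative") {
    if (is.null(absoluteScale))
      stop("relative illuminant: an explicit 'absoluteScale' factor is ",
           "required to obtain absolute photon flux")
    E <- E * absoluteScale
  }
  wl <- wavelengths(illum)
  N <- E * (wl * 1e-9) / (.PLANCK * .LIGHTSPEED)
  Illuminant(Spectrum(N, wl, kind = "irradiance-photon",
                      label = specLabel(illum)), scale = "absolute")
}

#' CIE D65 standard daylight illuminant
#'
#' The CIE D65 relative spectral power distribution (5 nm tabulation, 300 to
#' 800 nm, normalized to 100 at 560 nm), interpolated onto the requested
#' grid. Bundled as a constant so no network access is ever needed.
#'
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A relative, energy-basis [Illuminant-class].
#' @examples
#' intensities(d65())[wavelengths(d65()) == 560]  # 100 by convention
#' @export
d65 <- function(grid = defaultGrid()) {
  s <- Spectrum(.D65_SPD, .D65_WL, kind = "irradiance-energy", label = "D65")
  Illuminant(resampleSpectrum(s, grid), scale = "relative")
}

.D65_WL <- seq(300, 800, 5)
.D65_SPD <- c(
  0.0341, 1.6643, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535, 38.5011,
  39.9488, 42.4302, 44.9117, 45.7750, 46.6383, 49.3637, 52.0891, 51.0323,
  49.9755, 52.3118, 54.6482, 68.7015, 82.7549, 87.1204, 91.4860, 92.4589,
  93.4318, 90.0570, 86.6823, 95.7736, 104.8650, 110.9360, 117.0080,
  117.4100, 117.8120, 116.3360, 114.8610, 115.3920, 115.9230, 112.3670,
  108.8110, 109.0820, 109.3540, 108.5780, 107.8020, 106.2960, 104.7900,
  106.2390, 107.6890, 106.0470, 104.4050, 104.2250, 104.0460, 102.0230,
  100.0000, 98.1671, 96.3342, 96.0611, 95.7880, 92.2368, 88.6856, 89.3459,
  90.0062, 89.8026, 89.5991, 88.6489, 87.6987, 85.4936, 83.2886, 83.4939,
  83.6992, 81.8630, 80.0268, 80.1207, 80.2146, 81.2462, 82.2778, 80.2810,
  78.2842, 74.0027, 69.7213, 70.6652, 71.6091, 72.9790, 74.3490, 67.9765,
  61.6040, 65.7448, 69.8856, 72.4863, 75.0870, 69.3398, 63.5927, 55.0054,
  46.4182, 56.6118, 66.8054, 65.0941, 63.3828, 63.8434, 64.3040, 61.8779,
  59.4519)

#' Fraction of illuminant flux within a wavelength band
#'
#' Trapezoidal integral of the illuminant over `band` divided by the
#' integral over `total`. The basis argument selects whether flux is counted
#' as photons (multiplying an energy spectrum by wavelength) or as energy
#' (dividing a photon spectrum by wavelength); constants cancel in the
#' ratio, so relative illuminants are fine.
#'
#' @param illum an [Illuminant-class].
#' @param band numeric length-2, band limits in nm, within `total`.
#' @param total numeric length-2, reference range in nm, within the grid.
#' @param basis `"photon"` (default) or `"energy"`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' bandFraction(d65(), c(300, 500), basis = "energy")  # ~0.37
#' @export
bandFraction <- function(illum, band, total = c(300, 800),
                         basis = c("photon", "energy")) {
  stopifnot(is(illum, "Illuminant"), length(band) == 2L, length(total) == 2L)
  basis <- match.arg(basis)
  if (band[1L] < total[1L] || band[2L] > total[2L])
    stop("band must lie within total")
  wl <- wavelengths(illum)
  if (total[1L] < min(wl) || total[2L] > max(wl))
    stop("total range must lie within the illuminant grid")
  v <- intensities(illum)
  if (basis == "photon" && specKind(illum) == "irradiance-energy")
    v <- v * wl
  if (basis == "energy" && specKind(illum) == "irradiance-photon")
    v <- v / wl
  integ <- function(lo, hi) {
    keep <- wl > lo & wl < hi
    x <- c(lo, wl[keep], hi)
    y <- stats::approx(wl, v, xout = x)$y
    trapz(x, y)
  }
  integ(band[1L], band[2L]) / integ(total[1L], total[2L])
}
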