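#' @include visual-systems.R
NULL

#' Quantum catch of a photoreceptor
#'
#' Q = integral of R(lambda) * I(lambda) * S(lambda) d lambda over the
#' common grid (trapezoid rule): the photon (or energy) flux absorbed by a
#' receptor viewing a reflecting surface under an illuminant.
#'
#' @param receptor a [ReceptorSensitivity-class].
#' @param reflectance a reflectance [Spectrum-class].
#' @param illum an [Illuminant-class].
#' @return Nonnegative catch (units follow the illuminant basis).
#' @export
quantumCatch <- function(receptor, reflectance, illum) {
  wl <- wavelengths(receptor)
  if (!identical(wl, wavelengths(reflectance)) ||
      !identical(wl, wavelengths(illum)))
    stop("receptor, reflectance and illuminant must share one grid")
  trapz(wl, intensities(receptor) * intensities(reflectance) *
            intensities(illum))
}

#' von Kries chromatic adaptation
#'
#' Normalizes a catch by the catch of the same receptor class for the
#' adapting background (here, typically mean foliage): q = Q / Q_bg.
#'
#' @param Q stimulus catch(es).
#' @param Qbg background catch(es), > 0.
#' @return Adapted catch(es).
#' @export
vonKries <- function(Q, Qbg) {
  if (any(Qbg <= 0))
    stop("degenerate background: background catch must be positive")
  Q / Qbg
}

#' Generalized receptor-noise-limited contrast
#'
#' The n-receptor form of the receptor-noise-limited discriminability:
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\prod_{k \notin \{i,j\}} e_k)^2
#'   (\Delta f_i - \Delta f_j)^2}{\sum_i (\prod_{k \ne i} e_k)^2}}
#' which reduces to the familiar di-, tri- and tetrachromat closed forms.
#' Depends only on pairwise differences of the per-class log signals, so a
#' common offset (an achromatic intensity change) leaves it untouched.
#'
#' @param deltaF per-class log-signal differences.
#' @param noise per-class noise values e_i, all > 0.
#' @return Contrast in JND (nonnegative scalar).
#' @export
rnlDeltaS <- function(deltaF, noise) {
  n <- length(deltaF)
  stopifnot(n >= 2L, length(noise) == n, all(noise > 0))
  deltaF <- unname(deltaF)
  noise <- unname(noise)
  num <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    num <- num + prod(noise[-c(i, j)])^2 * (deltaF[i] - deltaF[j])^2
  }
  den <- sum(vapply(seq_len(n), function(i) prod(noise[-i])^2, numeric(1)))
  sqrt(num / den)
}

# Catch matrix: one row per receptor class, one column per spectrum.
# Vectorized core shared by chromaticContrast and the pairwise pipeline.
catchMatrix <- function(system, spectra, illum) {
  wl <- wavelengths(system@receptors[[1L]])
  w <- trapzWeights(wl)
  Iw <- intensities(illum) * w
  S <- vapply(receptors(system), intensities, numeric(length(wl)))
  R <- vapply(spectra, function(s) {
    if (!identical(wavelengths(s), wl))
      stop("all spectra must share the visual system's grid")
    intensities(s)
  }, numeric(length(wl)))
  R <- matrix(R, nrow = length(wl))
  Q <- t(S * Iw) %*% R   # classes x spectra
  rownames(Q) <- names(receptors(system))
  colnames(Q) <- vapply(spectra, specLabel, character(1))
  Q
}

# Floor near-zero catches at floorRatio x the largest class catch of the
# same stimulus, so idealized spectra (e.g. pure black) stay in the log
# domain; warns when the floor engages.
floorCatches <- function(Q, floorRatio = 1e-12, context = "stimulus") {
  colmax <- apply(Q, 2L, max)
  if (max(colmax) == 0)
    stop("all catches are zero: stimuli carry no light in any class")
  # an identically zero stimulus still gets a floor, scaled by the
  # brightest stimulus in the call
  colmax[colmax == 0] <- max(colmax)
  floors <- floorRatio * colmax
  low <- sweep(Q, 2L, floors, "<")
  if (any(low)) {
    cls <- rownames(Q)[which(low, arr.ind = TRUE)[, 1L]]
    warning(sprintf(
      "near-zero %s catch floored in class(es): %s", context,
      paste(unique(cls), collapse = ", ")))
    Q <- pmax(Q, matrix(floors, nrow = nrow(Q), ncol = ncol(Q),
                        byrow = TRUE))
  }
  Q
}

#' Chromatic contrast between two reflectance spectra
#'
#' Runs the full receptor-noise-limited model for one spectrum pair: quantum
#' catches of each receptor class for both stimuli and the adapting
#' background, von Kries adaptation, log (Fechner) signals, per-class noise
#' (neural, or neural plus photon shot noise in quantum mode), and the
#' generalized n-receptor contrast.
#'
#' In quantum mode the illuminant must be an absolute photon-flux spectrum;
#' absolute catches are `kappa` times the spectral integral, with `kappa`
#' the eye's effective aperture-times-integration-time constant (m^2 s).
#' The default 1e-14 corresponds to a facet-sized aperture (~5e-10 m^2), a
#' ~0.1 s integration time, ~0.5 combined optical and quantum efficiency,
#' and the ~1 degree acceptance angle of a single rhabdom viewing an
#' extended surface.
#'
#' @param system a [VisualSystem-class].
#' @param reflA,reflB reflectance [Spectrum-class] objects.
#' @param background adapting reflectance [Spectrum-class] (e.g. mean
#'   foliage).
#' @param illum an [Illuminant-class].
#' @param kappa photon-catch scaling for quantum mode (m^2 s).
#' @param floorRatio near-zero catch floor, as a fraction of the largest
#'   class catch of the same stimulus.
#' @return A [ContrastResult-class].
#' @examples
#' sys <- buildNamedSystem("USML")
#' leaf <- genLeaf(label = "leaf")
#' flower <- genFlower(550, label = "flower")
#' deltaS(chromaticContrast(sys, flower, leaf, leaf, d65()))
#' @export
chromaticContrast <- function(system, reflA, reflB, background, illum,
                              kappa = 1e-14, floorRatio = 1e-12) {
  quantum <- noiseMode(system) == "quantum"
  if (quantum && (illum@scale != "absolute" ||
                  specKind(illum) != "irradiance-photon"))
    stop("quantum noise mode requires an absolute photon-flux illuminant")
  Q <- catchMatrix(system, list(reflA, reflB, background), illum)
  if (any(Q[, 3L] <= 0))
    stop("degenerate background: background catch must be positive in ",
         "every receptor class")
  Qs <- floorCatches(Q[, 1:2, drop = FALSE], floorRatio)
  qA <- vonKries(Qs[, 1L], Q[, 3L])
  qB <- vonKries(Qs[, 2L], Q[, 3L])
  df <- log(qA) - log(qB)
  e <- if (quantum)
    receptorNoise(system, kappa * Qs[, 1L], kappa * Qs[, 2L])
  else receptorNoise(system)
  new("ContrastResult",
      pair = c(specLabel(reflA), specLabel(reflB)),
      deltaF = df, noise = e, deltaS = rnlDeltaS(df, e))
}
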