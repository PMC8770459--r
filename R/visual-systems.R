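#' @include pigments.R
NULL

.CLASS_ORDER <- c("UVS", "SWS", "MWS", "LWS")

#' Relative receptor-density presets
#'
#' Relative photoreceptor densities (UVS, SWS, MWS, LWS) used by the
#' contrast models. `"beetle"` is the jewel-beetle opsin-expression-based
#' default (1.14, 1, 1.26, 1.38); `"papilio"` and `"heliconius"` are
#' published butterfly ratios spanning the known variation in tetrachromatic
#' insects.
#'
#' @param name preset name.
#' @return Named numeric vector of densities for the four classes.
#' @export
densityPreset <- function(name = c("beetle", "papilio", "heliconius")) {
  name <- match.arg(name)
  switch(name,
    beetle = c(UVS = 1.14, SWS = 1.00, MWS = 1.26, LWS = 1.38),
    papilio = c(UVS = 1.00, SWS = 1.00, MWS = 4.08, LWS = 2.92),
    heliconius = c(UVS = 1.00, SWS = 1.44, MWS = 2.22, LWS = 11.11))
}

#' Redistribute densities onto a subset of receptor classes
#'
#' When a receptor class is removed (trichromat vs tetrachromat), its
#' photoreceptors are redistributed proportionally among the remaining
#' classes so that the total receptor count per integrative unit — and the
#' noise of each individual photoreceptor — stays the same. Each kept
#' density is scaled by sum(full) / sum(kept), conserving the total.
#'
#' @param full named numeric vector of densities over all classes.
#' @param kept character vector naming the classes to keep.
#' @return Named numeric vector over `kept`, summing to `sum(full)`.
#' @examples
#' redistributeDensities(densityPreset("beetle"), c("UVS", "SWS", "LWS"))
#' @export
redistributeDensities <- function(full, kept) {
  stopifnot(length(kept) >= 1L, all(kept %in% names(full)))
  full[kept] * sum(full) / sum(full[kept])
}

#' Single-receptor noise from a Weber fraction
#'
#' The receptor-noise model specifies the Weber fraction omega_i of a class
#' through omega_i = nu / sqrt(eta_i): noise falls with the square root of
#' the number of receptors pooled. Anchoring omega = 0.12 at the
#' tetrachromat's LWS class (eta = 1.38) fixes the single-receptor noise
#' nu = 0.12 * sqrt(1.38), which is then shared by every visual system so
#' that individual photoreceptors are equally noisy everywhere.
#'
#' @param weber Weber fraction of the reference class (default 0.12).
#' @param referenceDensity relative density of the reference class (default
#'   1.38, the tetrachromat LWS).
#' @return The single-receptor noise nu.
#' @export
deriveNu <- function(weber = 0.12, referenceDensity = 1.38) {
  stopifnot(weber > 0, referenceDensity > 0)
  weber * sqrt(referenceDensity)
}

#' Per-class receptor noise of a visual system
#'
#' Neural mode: e_i = nu / sqrt(eta_i), the Weber fraction of each pooled
#' class. Quantum mode adds photon shot noise from the finite absolute
#' photon catches of the two stimuli being compared:
#' e_i = sqrt(nu^2 / eta_i + 2 / (Q_i^A + Q_i^B)).
#'
#' @param system a [VisualSystem-class].
#' @param catchesA,catchesB absolute photon catches of the two stimuli, one
#'   value per receptor class; required in quantum mode.
#' @return Named numeric vector of noise values e_i.
#' @export
receptorNoise <- function(system, catchesA = NULL, catchesB = NULL) {
  stopifnot(is(system, "VisualSystem"))
  eta <- densities(system)
  neural <- system@nu / sqrt(eta)
  if (noiseMode(system) == "neural") return(neural)
  if (is.null(catchesA) || is.null(catchesB))
    stop("quantum noise mode requires absolute photon catches of both ",
         "stimuli")
  stopifnot(length(catchesA) == length(eta),
            length(catchesB) == length(eta))
  sqrt(neural^2 + 2 / (catchesA + catchesB))
}

# Peak wavelengths (nm) of the named hypothetical systems. The base set
# {355, 445, 530, 600} holds the representative insect UVS/SWS/MWS/LWS
# medians; VSxxx sweeps the LWS peak; EVEN is the evenly-spaced control.
.NAMED_LAMBDA <- list(
  USM  = c(UVS = 355, SWS = 445, MWS = 530),
  UML  = c(UVS = 355, MWS = 530, LWS = 600),
  USL  = c(UVS = 355, SWS = 445, LWS = 600),
  USML = c(UVS = 355, SWS = 445, MWS = 530, LWS = 600),
  VS580 = c(UVS = 355, SWS = 445, MWS = 530, LWS = 580),
  VS600 = c(UVS = 355, SWS = 445, MWS = 530, LWS = 600),
  VS620 = c(UVS = 355, SWS = 445, MWS = 530, LWS = 620),
  VS640 = c(UVS = 355, SWS = 445, MWS = 530, LWS = 640),
  VS660 = c(UVS = 355, SWS = 445, MWS = 530, LWS = 660),
  EVEN = c(UVS = 355, SWS = 455, MWS = 560, LWS = 660))

#' Build a named hypothetical visual system
#'
#' Assembles the tri- and tetrachromatic systems studied by the contrast
#' models. `USM`, `UML` and `USL` are trichromats obtained by dropping one
#' class from the tetrachromat `USML` (peaks 355, 445, 530, 600 nm), with
#' densities proportionally redistributed; `VS580`--`VS660` sweep the
#' tetrachromat's LWS peak; `EVEN` is an evenly-spaced control (355, 455,
#' 560, 660 nm). Receptors peaking beyond 570 nm — past the longest known A1
#' pigment — are built by the requested red-shift mechanism; all others come
#' straight from the A1 template. The single-receptor noise `nu` is anchored
#' at the tetrachromat's LWS Weber fraction and shared across systems.
#'
#' @param name system name, see Details.
#' @param mech red-shift mechanism for receptors beyond 570 nm:
#'   `"filter"` (screening pigment) or `"opsin"` (template shift).
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @param densityFull named densities of the full four-class set (default
#'   [densityPreset]`("beetle")`).
#' @param weber Weber fraction anchoring the reference (LWS) class.
#' @param noiseMode `"neural"` or `"quantum"`.
#' @param filterSlope logistic filter steepness in nm^-1 for the
#'   filter-shift mechanism.
#' @return A [VisualSystem-class].
#' @examples
#' buildNamedSystem("USML")
#' @export
buildNamedSystem <- function(name, mech = c("filter", "opsin"),
                             grid = defaultGrid(),
                             densityFull = densityPreset("beetle"),
                             weber = 0.12,
                             noiseMode = c("neural", "quantum"),
                             filterSlope = 0.1) {
  mech <- match.arg(mech)
  noiseMode <- match.arg(noiseMode)
  if (!name %in% names(.NAMED_LAMBDA))
    stop(sprintf("unknown visual system '%s'; known: %s", name,
                 paste(names(.NAMED_LAMBDA), collapse = ", ")))
  lm <- .NAMED_LAMBDA[[name]]
  stopifnot(identical(names(densityFull), .CLASS_ORDER))
  dens <- redistributeDensities(densityFull, names(lm))
  recs <- lapply(lm, function(l) {
    if (l > 570) {
      if (mech == "filter")
        filterShiftedReceptor(l, baseLambdaMax = 570, slope = filterSlope,
                              grid = grid)
      else opsinShiftedReceptor(l, grid = grid)
    } else a1Template(l, grid = grid)
  })
  VisualSystem(recs, dens,
               nu = deriveNu(weber, densityFull[["LWS"]]),
               noiseMode = noiseMode, label = name)
}

#' Serialize a visual system to a JSON config
#'
#' Writes everything needed to rebuild the system: per-class name, nominal
#' peak, generating mechanism (and filter slope where applicable), density,
#' plus the shared noise parameter and noise mode.
#'
#' @param system a [VisualSystem-class].
#' @param path output JSON file path.
#' @return Invisibly, `path`.
#' @seealso [readSystemConfig()]
#' @export
writeSystemConfig <- function(system, path) {
  stopifnot(is(system, "VisualSystem"))
  recs <- receptors(system)
  cfg <- list(
    label = specLabel(system),
    noiseMode = noiseMode(system),
    nu = system@nu,
    classes = data.frame(
      name = names(recs),
      lambdaMax = vapply(recs, lambdaMax, numeric(1)),
      mechanism = vapply(recs, mechanism, character(1)),
      filterSlope = vapply(recs, function(r) r@filterSlope, numeric(1)),
      density = unname(densities(system)),
      row.names = NULL))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Rebuild a visual system from a JSON config
#'
#' @param path JSON file written by [writeSystemConfig()].
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return A [VisualSystem-class].
#' @export
readSystemConfig <- function(path, grid = defaultGrid()) {
  cfg <- jsonlite::fromJSON(path)
  cl <- cfg$classes
  recs <- lapply(seq_len(nrow(cl)), function(i) {
    switch(cl$mechanism[i],
      "template" = a1Template(cl$lambdaMax[i], grid),
      "opsin-shifted" = opsinShiftedReceptor(cl$lambdaMax[i], grid),
      "filter-shifted" = filterShiftedReceptor(
        cl$lambdaMax[i], slope = as.numeric(cl$filterSlope[i]),
        grid = grid),
      stop("unknown mechanism in config: ", cl$mechanism[i]))
  })
  names(recs) <- cl$name
  dens <- stats::setNames(as.numeric(cl$density), cl$name)
  VisualSystem(recs, dens, nu = cfg$nu, noiseMode = cfg$noiseMode,
               label = cfg$label)
}
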