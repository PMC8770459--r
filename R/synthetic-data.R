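#' @include spectra-io.R
NULL

# Additive clipped Gaussian measurement noise, emulating replicate
# spectrometer variability.
add_noise <- function(v, noiseSd, seed) {
  if (noiseSd > 0)
    v <- v + with_seed_or_not(seed, stats::rnorm(length(v), 0, noiseSd))
  clip01(v)
}

#' Synthetic flower reflectance
#'
#' Sigmoidal reflectance — a sharp rise at the inflection wavelength and a
#' long-wavelength plateau, the commonest flower spectral shape — with an
#' optional ultraviolet Gaussian bump and additive clipped measurement
#' noise.
#'
#' @param lambdaInfl inflection wavelength in nm.
#' @param slope sigmoid steepness in nm^-1.
#' @param rMin,rMax reflectance floor and plateau, `0 <= rMin < rMax <= 1`.
#' @param uvBump optional `c(center, width, height)` Gaussian UV reflectance
#'   bump.
#' @param noiseSd Gaussian noise standard deviation (reflectance units).
#' @param seed optional RNG seed for the noise draw.
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @param label sample label.
#' @return A reflectance [Spectrum-class], values in `[0, 1]`.
#' @export
genFlower <- function(lambdaInfl, slope = 0.1, rMin = 0.05, rMax = 0.8,
                      uvBump = NULL, noiseSd = 0, seed = NULL,
                      grid = defaultGrid(), label = "flower") {
  if (!(rMin >= 0 && rMin < rMax && rMax <= 1))
    stop("need 0 <= rMin < rMax <= 1")
  wl <- as_wl(grid)
  v <- rMin + (rMax - rMin) * stats::plogis(slope * (wl - lambdaInfl))
  if (!is.null(uvBump)) {
    stopifnot(length(uvBump) == 3L)
    v <- v + uvBump[3L] * exp(-((wl - uvBump[1L]) / uvBump[2L])^2)
  }
  Spectrum(add_noise(v, noiseSd, seed), wl, kind = "reflectance",
           label = label)
}

#' Synthetic leaf reflectance
#'
#' Foliage spectrum: low baseline, a chlorophyll-window green peak between
#' 500 and 600 nm, and the "red edge" — a steep logistic rise at about 690
#' nm up to a near-infrared plateau set by leaf internal scattering.
#'
#' @param greenCenter,greenWidth,greenHeight Gaussian green-peak parameters
#'   (nm, nm, reflectance).
#' @param redEdgeCenter red-edge midpoint in nm (about 690).
#' @param redEdgeSlope red-edge steepness in nm^-1.
#' @param nirPlateau near-infrared plateau reflectance; must exceed
#'   `baseline + greenHeight`.
#' @param baseline reflectance floor.
#' @param noiseSd,seed,grid,label as in [genFlower()].
#' @return A reflectance [Spectrum-class], values in `[0, 1]`.
#' @export
genLeaf <- function(greenCenter = 550, greenWidth = 40, greenHeight = 0.15,
                    redEdgeCenter = 690, redEdgeSlope = 0.15,
                    nirPlateau = 0.5, baseline = 0.05, noiseSd = 0,
                    seed = NULL, grid = defaultGrid(), label = "leaf") {
  if (!(baseline < baseline + greenHeight &&
        baseline + greenHeight < nirPlateau))
    stop("need baseline < baseline + greenHeight < nirPlateau")
  wl <- as_wl(grid)
  v <- baseline +
    greenHeight * exp(-((wl - greenCenter) / greenWidth)^2) +
    nirPlateau * stats::plogis(redEdgeSlope * (wl - redEdgeCenter))
  Spectrum(add_noise(v, noiseSd, seed), wl, kind = "reflectance",
           label = label)
}

#' Synthetic beetle reflectance
#'
#' Three stylized jewel-beetle colour mechanisms: `"pigment"` — a sigmoidal
#' long-pass-like curve (red/orange/yellow pigmentary colours, varying
#' mostly beyond 500 nm); `"structural"` — a narrow Gaussian peak
#' (interference colours); `"black"` — flat low reflectance.
#'
#' @param style `"pigment"`, `"structural"` or `"black"`.
#' @param peak pigment inflection / structural peak wavelength in nm (must
#'   lie on the grid).
#' @param width structural Gaussian width in nm (<= 50; narrow by
#'   construction).
#' @param height reflectance amplitude above baseline.
#' @param baseline reflectance floor (<= 0.1 for `"black"`).
#' @param pigmentSlope sigmoid steepness for the pigment style (nm^-1).
#' @param noiseSd,seed,grid,label as in [genFlower()].
#' @return A reflectance [Spectrum-class], values in `[0, 1]`.
#' @export
genBeetle <- function(style = c("pigment", "structural", "black"),
                      peak = 600, width = 30, height = 0.5,
                      baseline = 0.05, pigmentSlope = 0.05, noiseSd = 0,
                      seed = NULL, grid = defaultGrid(), label = "beetle") {
  style <- match.arg(style)
  wl <- as_wl(grid)
  if (style != "black") {
    if (is.na(peak) || peak < min(wl) || peak > max(wl))
      stop("peak must lie on the grid")
    stopifnot(width > 0)
  }
  v <- switch(style,
    pigment = baseline + height * stats::plogis(pigmentSlope * (wl - peak)),
    structural = {
      if (width > 50) stop("structural peaks are narrow: width <= 50 nm")
      baseline + height * exp(-((wl - peak) / width)^2)
    },
    black = {
      if (baseline > 0.1) stop("black style needs baseline <= 0.1")
      rep(baseline, length(wl))
    })
  Spectrum(add_noise(v, noiseSd, seed), wl, kind = "reflectance",
           label = label)
}

#' Synthetic civil-twilight illuminant
#'
#' Twilight sky light carries proportionally more blue (ozone-window
#' scattered light) and more red than daylight, with a pronounced green
#' trough. The generator reweights the photon-basis D65 shape with two
#' smooth Gaussian boosts; the default weights place 42% of 300--800 nm
#' photons in 300--500 nm and 41% in 650--800 nm (vs 28% and 34% for
#' photon-basis D65). The spectrum is scaled to a stated absolute total
#' photon flux, as photon-limited (shot-noise) modelling requires.
#'
#' @param blueWeight,redWeight amplitudes of the 400 nm and 740 nm Gaussian
#'   boosts applied to the photon-basis D65 shape.
#' @param absoluteScale total photon flux over 300--800 nm, photons s-1
#'   m-2. The default 1e16 is a plausible civil-twilight figure (roughly
#'   four to five orders of magnitude below full daylight).
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return An absolute photon-basis [Illuminant-class].
#' @export
genTwilight <- function(blueWeight = 4.5216, redWeight = 3.1075,
                        absoluteScale = 1e16, grid = defaultGrid()) {
  stopifnot(blueWeight >= 0, redWeight >= 0, absoluteScale >= 0)
  wl <- as_wl(grid)
  E <- intensities(d65(grid))
  shape <- (E * wl) * (1 + blueWeight * exp(-((wl - 400) / 70)^2) +
                         redWeight * exp(-((wl - 740) / 60)^2))
  v <- shape * absoluteScale / trapz(wl, shape)
  Illuminant(Spectrum(v, wl, kind = "irradiance-photon",
                      label = "twilight"), scale = "absolute")
}

#' DatasetSpec: sizes, seed and parameter ranges of a synthetic dataset
#'
#' @slot nBeetles,nFlowers,nLeaves sample counts (defaults 37, 47, 46, the
#'   sizes of the measured beetle / flower / leaf collections the generator
#'   emulates).
#' @slot seed integer RNG seed.
#' @slot ranges named list of per-generator parameter ranges.
#' @export
setClass("DatasetSpec",
  representation(nBeetles = "numeric", nFlowers = "numeric",
                 nLeaves = "numeric", seed = "numeric", ranges = "list"),
  validity = function(object) {
    if (any(c(object@nBeetles, object@nFlowers, object@nLeaves) < 1))
      "counts must be >= 1" else TRUE
  })

# Default parameter ranges: chosen to echo the qualitative spread of
# measured flower, leaf and beetle spectra (inflections across the visible
# range for flowers, modest green peaks and strong near-infrared plateaus
# for leaves, pigmentary / structural / black beetle colour mechanisms).
.DEFAULT_RANGES <- list(
  flower = list(lambdaInfl = c(380, 640), slope = c(0.05, 0.15),
                rMin = c(0, 0.1), rMax = c(0.5, 0.95), uvBumpProb = 0.3,
                uvCenter = 350, uvWidth = 25, uvHeight = c(0.1, 0.3)),
  leaf = list(greenCenter = c(540, 560), greenWidth = c(30, 50),
              greenHeight = c(0.1, 0.2), redEdgeCenter = c(688, 692),
              redEdgeSlope = c(0.12, 0.18), nirPlateau = c(0.4, 0.6),
              baseline = c(0.03, 0.07)),
  beetle = list(styleProbs = c(pigment = 0.5, structural = 0.35,
                               black = 0.15),
                pigmentPeak = c(450, 650), structuralPeak = c(350, 700),
                width = c(20, 50), height = c(0.3, 0.7),
                baseline = c(0.02, 0.1), blackBaseline = c(0.02, 0.08)),
  noiseSd = 0.005)

#' Specify a synthetic dataset
#'
#' @param nBeetles,nFlowers,nLeaves sample counts; defaults 37, 47 and 46.
#' @param seed integer RNG seed.
#' @param ranges parameter-range list; see the package source for the
#'   default structure.
#' @return A [DatasetSpec-class].
#' @export
DatasetSpec <- function(nBeetles = 37, nFlowers = 47, nLeaves = 46,
                        seed = 1, ranges = .DEFAULT_RANGES) {
  new("DatasetSpec", nBeetles = nBeetles, nFlowers = nFlowers,
      nLeaves = nLeaves, seed = seed, ranges = ranges)
}

runif1 <- function(r) stats::runif(1L, r[1L], r[2L])

# Draw one manifest row of generating parameters for a given sample type.
draw_params <- function(type, label, ranges, seed) {
  noiseSd <- ranges$noiseSd
  base <- data.frame(type = type, label = label, style = NA_character_,
                     lambdaInfl = NA_real_, slope = NA_real_,
                     rMin = NA_real_, rMax = NA_real_, uvCenter = NA_real_,
                     uvWidth = NA_real_, uvHeight = NA_real_,
                     greenCenter = NA_real_, greenWidth = NA_real_,
                     greenHeight = NA_real_, redEdgeCenter = NA_real_,
                     redEdgeSlope = NA_real_, nirPlateau = NA_real_,
                     baseline = NA_real_, peak = NA_real_,
                     width = NA_real_, height = NA_real_,
                     noiseSd = noiseSd, seed = seed,
                     stringsAsFactors = FALSE)
  if (type == "flower") {
    r <- ranges$flower
    base$lambdaInfl <- runif1(r$lambdaInfl)
    base$slope <- runif1(r$slope)
    base$rMin <- runif1(r$rMin)
    base$rMax <- runif1(r$rMax)
    if (stats::runif(1L) < r$uvBumpProb) {
      base$uvCenter <- r$uvCenter
      base$uvWidth <- r$uvWidth
      base$uvHeight <- runif1(r$uvHeight)
    }
  } else if (type == "leaf") {
    r <- ranges$leaf
    base$greenCenter <- runif1(r$greenCenter)
    base$greenWidth <- runif1(r$greenWidth)
    base$greenHeight <- runif1(r$greenHeight)
    base$redEdgeCenter <- runif1(r$redEdgeCenter)
    base$redEdgeSlope <- runif1(r$redEdgeSlope)
    base$nirPlateau <- runif1(r$nirPlateau)
    base$baseline <- runif1(r$baseline)
  } else {
    r <- ranges$beetle
    style <- sample(names(r$styleProbs), 1L, prob = r$styleProbs)
    base$style <- style
    if (style == "pigment") {
      base$peak <- runif1(r$pigmentPeak)
      base$height <- runif1(r$height)
      base$baseline <- runif1(r$baseline)
      base$width <- 30
    } else if (style == "structural") {
      base$peak <- runif1(r$structuralPeak)
      base$width <- runif1(r$width)
      base$height <- runif1(r$height)
      base$baseline <- 0.05
    } else {
      base$baseline <- runif1(r$blackBaseline)
    }
  }
  base
}

#' Rebuild spectra from a dataset manifest
#'
#' The manifest records every generating parameter and per-spectrum noise
#' seed, so regeneration is bit-identical: the manifest is the dataset.
#'
#' @param manifest a manifest `data.frame` as produced by [genDataset()].
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return Named list of [Spectrum-class] objects in manifest order.
#' @export
spectraFromManifest <- function(manifest, grid = defaultGrid()) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    switch(m$type,
      flower = genFlower(m$lambdaInfl, m$slope, m$rMin, m$rMax,
        uvBump = if (!is.na(m$uvCenter))
          c(m$uvCenter, m$uvWidth, m$uvHeight),
        noiseSd = m$noiseSd, seed = m$seed, grid = grid, label = m$label),
      leaf = genLeaf(m$greenCenter, m$greenWidth, m$greenHeight,
        m$redEdgeCenter, m$redEdgeSlope, m$nirPlateau, m$baseline,
        noiseSd = m$noiseSd, seed = m$seed, grid = grid, label = m$label),
      beetle = genBeetle(m$style, peak = m$peak, width = m$width,
        height = m$height, baseline = m$baseline, noiseSd = m$noiseSd,
        seed = m$seed, grid = grid, label = m$label),
      stop("unknown manifest type: ", m$type))
  })
  names(out) <- manifest$label
  out
}

#' Generate a synthetic beetle / flower / leaf dataset
#'
#' Draws generator parameters from the spec's uniform ranges under the
#' spec's seed, records them in a manifest, and builds every spectrum from
#' the manifest, so identical seeds give bit-identical datasets and the
#' manifest alone reproduces the collection.
#'
#' @param spec a [DatasetSpec-class] (default [DatasetSpec()]).
#' @param grid target [WavelengthGrid-class] or wavelength vector.
#' @return List with elements `beetles`, `flowers`, `leaves` (named lists of
#'   [Spectrum-class]) and `manifest` (a `data.frame`).
#' @examples
#' ds <- genDataset(DatasetSpec(seed = 1))
#' lengths(ds[c("beetles", "flowers", "leaves")])
#' @export
genDataset <- function(spec = DatasetSpec(), grid = defaultGrid()) {
  stopifnot(is(spec, "DatasetSpec"))
  manifest <- with_seed_or_not(spec@seed, {
    rows <- list()
    plan <- rbind(
      data.frame(type = "beetle",
                 label = sprintf("beetle%02d", seq_len(spec@nBeetles))),
      data.frame(type = "flower",
                 label = sprintf("flower%02d", seq_len(spec@nFlowers))),
      data.frame(type = "leaf",
                 label = sprintf("leaf%02d", seq_len(spec@nLeaves))))
    seeds <- sample.int(2147483646L, nrow(plan))
    for (i in seq_len(nrow(plan)))
      rows[[i]] <- draw_params(plan$type[i], plan$label[i], spec@ranges,
                               seeds[i])
    do.call(rbind, rows)
  })
  all <- spectraFromManifest(manifest, grid)
  list(beetles = all[manifest$type == "beetle"],
       flowers = all[manifest$type == "flower"],
       leaves = all[manifest$type == "leaf"],
       manifest = manifest)
}

#' Write a dataset manifest as JSON
#'
#' @param manifest a manifest `data.frame` from [genDataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows", na = "null",
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset manifest from JSON
#'
#' @param path JSON file written by [writeManifest()].
#' @return A manifest `data.frame` usable with [spectraFromManifest()].
#' @export
readManifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  num <- setdiff(names(m), c("type", "label", "style"))
  for (col in num) m[[col]] <- as.numeric(m[[col]])
  m
}
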