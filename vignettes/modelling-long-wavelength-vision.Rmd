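---
title: "Modelling the value of long-wavelength sensitivity in insect vision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the value of long-wavelength sensitivity in insect vision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insectRNL)
```

## The question and the model

Insect long-wavelength-sensitive (LWS) photoreceptors rarely peak beyond
600 nm, and when they do, the shift is usually produced by a coloured
screening pigment acting as a long-pass filter over an ordinary A1 visual
pigment, more rarely by opsin-sequence changes. This package quantifies
what such receptors contribute to colour discrimination by simulating
hypothetical eyes viewing natural surfaces.

The discrimination model is the receptor-noise-limited (RNL) framework.
Its assumptions, in order of appearance in the computation:

1. **Quantum catch.** Each receptor class integrates reflectance x
   illuminant x sensitivity over wavelength. We use 300-800 nm at 1 nm and
   the trapezoid rule throughout.
2. **von Kries adaptation.** Catches are divided by the catch for an
   adapting background. Following field practice for phytophagous insects,
   the background is the pointwise mean of the foliage collection in the
   run, shared by all comparison groups. In neural-noise mode the
   background cancels exactly in the signal differences (the tests assert
   this numerically), so this convention matters only for reporting
   per-class signals, not for the contrasts.
3. **Fechner signals.** The receptor signal is the natural log of the
   adapted catch; a stimulus pair yields per-class differences
   `deltaF_i = ln(Q_i^A / Q_i^B)`.
4. **Noise-limited discriminability.** The scalar contrast in
   just-noticeable differences (JND) is the generalized n-receptor RNL
   form implemented in `rnlDeltaS()`; it reduces to the standard di-, tri-
   and tetrachromat closed forms, which the test suite checks against
   independently coded versions to 1e-12 on a thousand random draws.

The model deliberately stops at the receptors: no colour-opponent coding,
no achromatic channel, no spatial vision. A computed JND is an upper bound
on discriminability under ideal viewing; behavioural thresholds are
typically above the theoretical 1 JND.

## Receptor sensitivities

All sensitivities derive from the A1 visual-pigment nomogram (alpha band
parameterized by lambda-max plus the ultraviolet beta band, renormalized
to peak 1). The template is accepted for 330-700 nm, the range over which
its coefficients were fitted.

Receptors peaking beyond 570 nm - the longest known A1 pigment - must be
red-shifted by one of two mechanisms:

* **Filter shifting** multiplies the fixed 570 nm template by a logistic
  long-pass transmission `1 / (1 + exp(-slope (lambda - cut)))` and solves
  the cut by bisection so the product peaks at the requested wavelength.
  The peak is located on a 0.1 nm refined grid because on the raw 1 nm
  grid the argmax moves in quantized jumps, which would stall the
  bisection on plateaus. The default slope of 0.1 /nm yields filtered
  receptors with a steep short-wavelength flank and roughly one third the
  width of the corresponding template curve, matching the qualitative
  profile of known filtered insect LWS receptors; since published filter
  spectra are not available in tabulated form, the slope is a parameter
  and any result that depends on filter steepness should be reported
  together with it.
* **Opsin shifting** simply evaluates the template at the longer peak,
  giving a much broader curve. The two mechanisms therefore differ in
  curve width and overlap with neighbouring classes, which is what drives
  their different contrast outcomes.

Filtering in reality also costs absolute sensitivity; because the RNL
model uses relative sensitivities, that cost is intentionally not
modelled, and the curves are renormalized to peak 1 after filtering.

## Visual systems, densities and noise

The named systems use representative insect peak wavelengths: the
tetrachromat USML at 355/445/530/600 nm, trichromats USM, UML, USL formed
by deleting one class, sweep systems VS580-VS660 moving the LWS peak in
20 nm steps, and the evenly spaced control at 355/455/560/660 nm.

Relative densities default to 1.14 : 1 : 1.26 : 1.38 (UVS : SWS : MWS :
LWS), an opsin-expression-based jewel-beetle ratio; `densityPreset()` also
ships two butterfly ratios (Papilio-type 1 : 1 : 4.08 : 2.92,
Heliconius-type 1 : 1.44 : 2.22 : 11.11) spanning the known variation in
tetrachromatic insects.

When a class is deleted, its receptors are redistributed proportionally
among the remaining classes (`eta_i' = eta_i * sum(all) / sum(kept)`),
conserving the total of 4.78 receptors per integrative unit. Noise per
class follows `e_i = nu / sqrt(eta_i)`. The single-receptor noise `nu` is
the one free noise parameter; we anchor it so the tetrachromat's LWS class
has Weber fraction 0.12 (`nu = 0.12 * sqrt(1.38) ~ 0.141`) and reuse the
same `nu` in every system, which formalizes "equal noise per individual
photoreceptor" and makes redistribution strictly noise-reducing for the
surviving classes. The standard relation `omega_i = nu / sqrt(eta_i)` is
an interpretation on our part - for a trichromat lacking LWS there is no
LWS class to anchor to, and the shared-`nu` rule is the only convention
that keeps individual receptors identical across systems.

## Dim light: photon shot noise

Twilight runs switch the system to quantum noise mode,
`e_i = sqrt(nu^2 / eta_i + 2 / (Q_i^A + Q_i^B))`, with `Q` the *absolute*
photon catches of the two stimuli. This requires an absolute photon-flux
illuminant (enforced as a precondition, never by silent rescaling) and a
catch-scaling constant `kappa` (m^2 s) converting spectral photon
irradiance into photons caught per integration time. `kappa` lumps the
eye's optics; the default 1e-14 comes from a facet-sized aperture
(~5e-10 m^2), an integration time of ~0.1 s, combined optical and quantum
efficiency of ~0.5, and the ~2e-4 steradian-fraction seen by a single
rhabdom viewing an extended surface. Under the default twilight flux
(1e16 photons s-1 m-2 over 300-800 nm, a civil-twilight order of
magnitude) this yields catches of a few photons per receptor and
integration, which is exactly the regime where shot noise dominates and
chromatic contrasts collapse relative to daylight. Because `kappa` for any
real eye is uncertain to an order of magnitude, only the qualitative
statement - twilight contrasts are far below daylight contrasts and
decrease with available light - should be relied on; the tests assert the
monotonicity, not a particular JND.

## Illuminants

D65 is bundled as the standard CIE 5 nm table (300-800 nm, 100 at 560 nm)
and interpolated; no network access is ever required. `toPhotonFlux()`
converts energy to photon irradiance via `E * lambda / (h c)`.

`bandFraction()` reports the fraction of illuminant flux in a wavelength
band and takes a `basis` argument because the answer depends on whether
photons or energy are counted: for D65, 300-500 nm holds 36.7% of the
energy but only 28.2% of the photons. Published "percent of light in a
band" figures for daylight are consistent with the energy basis, so that
is what the acceptance checks use; the photon basis is the default
elsewhere because the downstream model counts photons.

The synthetic twilight illuminant reweights the photon-basis D65 shape
with smooth Gaussian boosts at 400 and 740 nm. Its default weights are
calibrated once so that 42% of 300-800 nm photons fall in 300-500 nm and
41% in 650-800 nm - the blue- and red-enrichment characteristic of civil
twilight, with the green trough produced by Chappuis-band ozone
absorption. It is a stylized stand-in, not a radiative-transfer model.

## The synthetic spectra generator

The generator exists so the full pipeline is testable and reproducible
without measured data. It emulates the *structural* features that drive
the contrast results:

* **Flowers**: sigmoidal reflectance (sharp rise at an inflection between
  380 and 640 nm, plateau 0.5-0.95), optionally a UV bump; the classic
  flower spectral shape.
* **Leaves**: low baseline, a modest green peak near 550 nm (height
  0.1-0.2), and the red edge - a steep logistic rise near 690 nm to a
  near-infrared plateau of 0.4-0.6.
* **Beetles**: three colour mechanisms - long-pass-like pigmentary curves
  with inflections 450-650 nm (so most variation sits beyond 500 nm),
  narrow structural (interference) peaks, and flat black - mixed roughly
  50/35/15.
* Additive Gaussian noise (sd 0.005 reflectance units, clipped to [0, 1])
  emulates replicate measurement variability.

Default collection sizes are 37 beetles, 47 flowers and 46 leaves,
matching the field collection the generator stands in for; a seeded run
therefore produces 1702-2162 pairs per comparison group. Every generated
spectrum's parameters and noise seed are recorded in a manifest, and
regenerating from the manifest is bit-identical.

What the generator does *not* reproduce: the actual measured spectra, their
covariance structure, iridescence and viewing-angle effects, or the exact
spectral diversity of any real community. Consequently, passing tests
establish that the pipeline recovers the correct *orderings* on data with
the right structure - which receptor combinations rank where, monotone
gains along the LWS sweep, filter- above opsin-shifting, twilight below
daylight - but the percentage differences printed by the acceptance script
are properties of the synthetic collection and drift with the seed.
Measured collections can be substituted through `readSpectraTable()`
without touching the rest of the pipeline.

## Numerical choices and degenerate inputs

* Grid 300-800 nm at 1 nm (501 points); integration by trapezoid; linear
  interpolation for resampling, with extrapolation refused.
* Negative values in read spectra files (spectrometer noise) are clamped
  to 0 with a warning.
* Near-zero catches - possible for UV receptors viewing idealized black
  spectra - are floored at 1e-12 times the largest class catch of the same
  stimulus (with a warning) before taking logs, so synthetic runs complete
  instead of erroring; an identically zero stimulus borrows the floor of
  the brightest stimulus in the call. The floor is far below any
  physically meaningful catch and does not perturb regular results.
* Bisection for the filter cut runs on [520, 870] nm to a 0.05 nm
  bracket; the solved cut increases strictly with the target peak.
* Statistical comparison between systems is descriptive (means, percent
  differences) plus a paired sign-flip permutation test on per-pair
  contrast differences. A mixed-model treatment of the crossed
  pair-sampling design is out of scope; the permutation test conditions
  on the pairs actually computed and keeps the package dependency-light.

## Known limitations

* Relative sensitivities only: the absolute-sensitivity cost of screening
  filters, and hence any intensity-threshold consequence, is not modelled.
* No opponent processing, no achromatic channel, no saturation of large
  JND values; reported JNDs above ~10 should be read as "very
  conspicuous" rather than linearly.
* The A2/A3 chromophore route to red sensitivity is not implemented
  (absent in insects).
* The twilight illuminant and `kappa` are order-of-magnitude constructs;
  quantum-mode outputs are comparative, not photometric predictions.
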