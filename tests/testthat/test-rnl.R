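test_that("quantum catch integrates R * I * S over the grid", {
  wl <- 300:800
  ones <- Spectrum(rep(1, 501L), wl, kind = "sensitivity", label = "S1")
  refl1 <- Spectrum(rep(1, 501L), wl, label = "white")
  refl0 <- Spectrum(rep(0, 501L), wl, label = "void")
  flat <- Illuminant(Spectrum(rep(1, 501L), wl, kind = "irradiance-energy"))
  expect_equal(quantumCatch(ones, refl1, flat), 500)
  expect_equal(quantumCatch(ones, refl0, flat), 0)
  # synthetic leaf under D65 with a 530 nm template vs naive loop integral
  leaf <- genLeaf(label = "leaf")
  r530 <- a1Template(530)
  got <- quantumCatch(r530, leaf, d65())
  oracle <- naive_trapz(wl, intensities(r530) * intensities(leaf) *
                              intensities(d65()))
  expect_equal(got, oracle, tolerance = 1e-12)
  short <- Spectrum(rep(1, 301L), 300:600, label = "short")
  expect_error(quantumCatch(r530, short, d65()), "grid")
})

test_that("von Kries adaptation divides by the background catch", {
  expect_equal(vonKries(3, 3), 1)
  expect_equal(vonKries(c(2, 4), c(2, 2)), c(1, 2))
  expect_equal(vonKries(6, 2), 3 * vonKries(2, 2))
  expect_error(vonKries(1, 0), "degenerate")
})

test_that("the generalized contrast reproduces the closed-form examples", {
  expect_equal(rnlDeltaS(c(0.3, 0.1), c(0.1, 0.2)), sqrt(0.04 / 0.05))
  expect_equal(rnlDeltaS(c(0.3, 0.1), c(0.1, 0.2)), 0.8944,
               tolerance = 1e-4)
  expect_equal(rnlDeltaS(c(0.1, 0.2, 0.3, 0.4), rep(0.1, 4L)), sqrt(5))
  expect_equal(rnlDeltaS(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3)), 0)
})

test_that("the generalized formula agrees with independent closed forms", {
  withr::with_seed(42, {
    for (rep in seq_len(300L)) {
      n <- sample(2:4, 1L)
      df <- stats::rnorm(n)
      e <- stats::runif(n, 0.05, 0.5)
      expect_equal(rnlDeltaS(df, e), oracle_closed_form(df, e),
                   tolerance = 1e-12)
    }
  })
})

test_that("identical stimuli have zero contrast and contrast is symmetric", {
  sys <- buildNamedSystem("USML")
  leaf <- genLeaf(label = "leaf")
  fl <- genFlower(520, label = "fl")
  bg <- genLeaf(nirPlateau = 0.45, label = "bg")
  expect_equal(deltaS(chromaticContrast(sys, leaf, leaf, bg, d65())), 0)
  ab <- chromaticContrast(sys, fl, leaf, bg, d65())
  ba <- chromaticContrast(sys, leaf, fl, bg, d65())
  expect_equal(deltaS(ab), deltaS(ba), tolerance = 1e-12)
  expect_equal(deltaF(ab), -deltaF(ba), tolerance = 1e-12)
})

test_that("neural-mode contrast cancels the adapting background", {
  sys <- buildNamedSystem("USL")
  a <- genFlower(450, label = "a")
  b <- genBeetle("pigment", peak = 560, label = "b")
  bg1 <- genLeaf(label = "bg1")
  bg2 <- genFlower(600, rMax = 0.6, label = "bg2")
  d1 <- deltaS(chromaticContrast(sys, a, b, bg1, d65()))
  d2 <- deltaS(chromaticContrast(sys, a, b, bg2, d65()))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("neural-mode contrast ignores illuminant scale; quantum mode does not", {
  a <- genFlower(450, label = "a")
  b <- genLeaf(label = "b")
  bg <- genLeaf(label = "bg")
  sysN <- buildNamedSystem("USML")
  ill <- d65()
  ill10 <- Illuminant(Spectrum(10 * intensities(ill), wavelengths(ill),
                               kind = "irradiance-energy", label = "D65x10"))
  expect_equal(deltaS(chromaticContrast(sysN, a, b, bg, ill)),
               deltaS(chromaticContrast(sysN, a, b, bg, ill10)),
               tolerance = 1e-12)
  sysQ <- buildNamedSystem("USML", noiseMode = "quantum")
  tw1 <- genTwilight(absoluteScale = 1e15)
  tw2 <- genTwilight(absoluteScale = 1e17)
  expect_lt(deltaS(chromaticContrast(sysQ, a, b, bg, tw1)),
            deltaS(chromaticContrast(sysQ, a, b, bg, tw2)))
})

test_that("scaling one reflectance changes no pairwise signal differences", {
  sys <- buildNamedSystem("USML")
  a <- genFlower(500, rMax = 0.9, label = "a")
  half <- Spectrum(0.5 * intensities(a), wavelengths(a), label = "a_half")
  b <- genLeaf(label = "b")
  bg <- genLeaf(label = "bg")
  d1 <- chromaticContrast(sys, a, b, bg, d65())
  d2 <- chromaticContrast(sys, half, b, bg, d65())
  expect_equal(deltaS(d1), deltaS(d2), tolerance = 1e-12)
  expect_equal(deltaF(d2) - deltaF(d1),
               rep(log(0.5), 4L), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("near-zero catches are floored with a warning instead of erroring", {
  sys <- buildNamedSystem("USML")
  black <- Spectrum(numeric(501L), label = "void")
  leaf <- genLeaf(label = "leaf")
  expect_warning(res <- chromaticContrast(sys, black, leaf, leaf, d65()),
                 "floored")
  expect_true(is.finite(deltaS(res)))
})

test_that("quantum mode rejects relative illuminants", {
  sysQ <- buildNamedSystem("USML", noiseMode = "quantum")
  a <- genFlower(450, label = "a")
  b <- genLeaf(label = "b")
  expect_error(chromaticContrast(sysQ, a, b, b, d65()),
               "absolute photon-flux")
})
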