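test_that("reading a wide table resamples to the grid and preserves endpoints", {
  wl5 <- seq(300, 800, 5)
  tab <- data.frame(wl = wl5, a = seq(0, 1, length.out = length(wl5)),
                    b = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  specs <- readSpectraTable(path)
  expect_named(specs, c("a", "b"))
  expect_length(intensities(specs$a), 501L)
  expect_equal(intensities(specs$a)[c(1L, 501L)], c(0, 1))
  expect_equal(intensities(specs$b), rep(0.5, 501L))
  # tabulated points are preserved exactly by linear interpolation
  on5 <- wavelengths(specs$a) %in% wl5
  expect_equal(intensities(specs$a)[on5], tab$a)
})

test_that("table reading enforces monotone wavelengths and grid coverage", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wl = c(300, 400, 350, 800), a = 1), path,
                   row.names = FALSE)
  expect_error(readSpectraTable(path), "ascending")
  utils::write.csv(data.frame(wl = seq(400, 700, 10), a = 0.5), path,
                   row.names = FALSE)
  expect_error(readSpectraTable(path), "range error")
})

test_that("negative readings are clamped to zero with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(wl = seq(300, 800, 5), a = -0.01), path,
                   row.names = FALSE)
  expect_warning(specs <- readSpectraTable(path), "clamped")
  expect_true(all(intensities(specs$a) == 0))
})

test_that("tab-separated tables are autodetected and round-trip", {
  specs <- list(genLeaf(label = "l1"), genFlower(500, label = "f1"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSpectraTable(specs, path, sep = "\t")
  back <- readSpectraTable(path)
  expect_equal(intensities(back$l1), intensities(specs[[1L]]))
  expect_equal(intensities(back$f1), intensities(specs[[2L]]))
})

test_that("resampling onto the same grid is the identity", {
  s <- genLeaf(label = "x")
  expect_identical(resampleSpectrum(s, defaultGrid()), s)
})

test_that("meanSpectrum averages pointwise and matches a naive oracle", {
  flat <- function(v, lab) Spectrum(rep(v, 501L), label = lab)
  m <- meanSpectrum(list(flat(0.2, "a"), flat(0.4, "b")))
  expect_equal(intensities(m), rep(0.3, 501L))
  one <- genLeaf(label = "solo")
  expect_equal(intensities(meanSpectrum(list(one))), intensities(one))
  leaves <- genDataset(DatasetSpec(nBeetles = 1, nFlowers = 1, nLeaves = 46,
                                   seed = 3))$leaves
  m46 <- intensities(meanSpectrum(leaves))
  oracle <- rep(0, 501L)
  for (s in leaves) oracle <- oracle + intensities(s)
  expect_equal(m46, oracle / 46, tolerance = 1e-12)
  expect_error(meanSpectrum(list()), "empty")
  mixed <- list(flat(0.2, "a"),
                Spectrum(rep(0.5, 501L), kind = "transmission"))
  expect_error(meanSpectrum(mixed), "kind")
})

test_that("photon-flux conversion applies E * lambda / (h c)", {
  wl <- 300:800
  E <- numeric(501L); E[wl == 500] <- 1
  ill <- Illuminant(Spectrum(E, wl, kind = "irradiance-energy"),
                    scale = "absolute")
  N <- intensities(toPhotonFlux(ill))
  expect_equal(N[wl == 500], 2.517e18, tolerance = 1e-3)
  expect_true(all(N[wl != 500] == 0))
  # zero in, zero out; linear in E
  zero <- Illuminant(Spectrum(numeric(501L), wl, kind = "irradiance-energy"),
                     scale = "absolute")
  expect_true(all(intensities(toPhotonFlux(zero)) == 0))
  ill2 <- Illuminant(Spectrum(2 * E, wl, kind = "irradiance-energy"),
                     scale = "absolute")
  expect_equal(intensities(toPhotonFlux(ill2)), 2 * N)
  # strictly increasing in wavelength for flat E
  flatE <- Illuminant(Spectrum(rep(1, 501L), wl, kind = "irradiance-energy"),
                      scale = "absolute")
  expect_true(all(diff(intensities(toPhotonFlux(flatE))) > 0))
  # relative input requires an explicit absolute factor
  rel <- Illuminant(Spectrum(E, wl, kind = "irradiance-energy"))
  expect_error(toPhotonFlux(rel), "absoluteScale")
  expect_equal(intensities(toPhotonFlux(rel, absoluteScale = 3)), 3 * N)
})

test_that("the bundled D65 matches the published table and conventions", {
  ill <- d65()
  wl <- wavelengths(ill)
  v <- intensities(ill)
  expect_equal(v[wl == 560], 100)           # CIE normalization
  expect_equal(v[wl == 400], 82.7549)       # published 5 nm values
  expect_equal(v[wl == 450], 117.008)
  expect_equal(v[wl == 700], 71.6091)
  expect_true(all(v > 0))
  expect_equal(specKind(ill), "irradiance-energy")
})

test_that("band fractions integrate correctly and partition to one", {
  wl <- 300:800
  flat <- Illuminant(Spectrum(rep(1, 501L), wl, kind = "irradiance-photon"),
                     scale = "absolute")
  expect_equal(bandFraction(flat, c(300, 500)), 0.4)
  expect_equal(bandFraction(flat, c(300, 800)), 1.0)
  ill <- d65()
  parts <- bandFraction(ill, c(300, 500)) +
    bandFraction(ill, c(500, 650)) + bandFraction(ill, c(650, 800))
  expect_equal(parts, 1, tolerance = 1e-9)
  expect_error(bandFraction(ill, c(200, 500)), "band")
  # basis matters: photon weighting shifts weight to long wavelengths
  expect_true(bandFraction(ill, c(650, 800), basis = "photon") >
              bandFraction(ill, c(650, 800), basis = "energy"))
})

test_that("spectrum validity rejects malformed curves", {
  expect_error(Spectrum(rep(-0.1, 501L)), "nonnegative")
  expect_error(Spectrum(rep(1.5, 501L), kind = "sensitivity"), "exceed")
  expect_error(Spectrum(c(NA, rep(0, 500L))), "finite")
  expect_error(Spectrum(rep(0.5, 3L), grid = c(300, 400)), "length")
})
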