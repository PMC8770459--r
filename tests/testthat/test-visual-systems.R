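test_that("density redistribution conserves the total and matches arithmetic", {
  full <- densityPreset("beetle")
  expect_equal(sum(full), 4.78)
  expect_equal(redistributeDensities(full, names(full)), full)
  usl <- redistributeDensities(full, c("UVS", "SWS", "LWS"))
  expect_equal(sum(usl), 4.78)
  expect_equal(unname(usl), c(1.14, 1, 1.38) * 4.78 / 3.52,
               tolerance = 1e-12)
  expect_equal(unname(usl), c(1.5481, 1.3580, 1.8740), tolerance = 1e-4)
  usm <- redistributeDensities(full, c("UVS", "SWS", "MWS"))
  expect_equal(unname(usm), c(1.6027, 1.4059, 1.7714), tolerance = 1e-4)
  expect_error(redistributeDensities(full, character(0)))
})

test_that("nu is anchored at the reference Weber fraction and density", {
  expect_equal(deriveNu(0.12, 1.38), 0.12 * sqrt(1.38))
  expect_equal(deriveNu(0.12, 1.38), 0.14097, tolerance = 1e-4)
  expect_equal(deriveNu(0.12, 1), 0.12)
  expect_error(deriveNu(-0.1, 1))
})

test_that("neural noise follows e_i = nu / sqrt(eta_i)", {
  sys <- buildNamedSystem("USML")
  e <- receptorNoise(sys)
  expect_equal(unname(e), c(0.1320, 0.1410, 0.1256, 0.1200),
               tolerance = 1e-3)
  # the reference class recovers its Weber fraction
  expect_equal(unname(e["LWS"]), 0.12, tolerance = 1e-15)
})

test_that("quantum noise converges to neural for large catches and shrinks with catch", {
  sys <- buildNamedSystem("USML", noiseMode = "quantum")
  neural <- buildNamedSystem("USML")
  big <- rep(1e12, 4L)
  expect_equal(receptorNoise(sys, big, big), receptorNoise(neural),
               tolerance = 1e-6)
  e_small <- receptorNoise(sys, rep(10, 4L), rep(10, 4L))
  e_large <- receptorNoise(sys, rep(100, 4L), rep(100, 4L))
  expect_true(all(e_small > e_large))
  expect_true(all(e_large > receptorNoise(neural)))
  expect_error(receptorNoise(sys), "absolute photon catches")
})

test_that("named systems carry the documented peak sets and densities", {
  usml <- buildNamedSystem("USML")
  expect_equal(unname(vapply(receptors(usml), lambdaMax, numeric(1))),
               c(355, 445, 530, 600))
  expect_equal(names(receptors(usml)), c("UVS", "SWS", "MWS", "LWS"))
  vs660 <- buildNamedSystem("VS660")
  expect_equal(lambdaMax(receptors(vs660)$LWS), 660)
  usl <- buildNamedSystem("USL")
  expect_length(receptors(usl), 3L)
  expect_equal(sum(densities(usl)), 4.78)
  even <- buildNamedSystem("EVEN")
  expect_equal(unname(vapply(receptors(even), lambdaMax, numeric(1))),
               c(355, 455, 560, 660))
  expect_error(buildNamedSystem("XYZ"), "unknown")
})

test_that("every named system conserves total density and shares one nu", {
  names <- c("USM", "UML", "USL", "USML", "VS580", "VS660", "EVEN")
  systems <- lapply(names, buildNamedSystem)
  expect_true(all(vapply(systems, function(s) sum(densities(s)),
                         numeric(1)) - 4.78 < 1e-12))
  nus <- vapply(systems, function(s) s@nu, numeric(1))
  expect_equal(nus, rep(0.12 * sqrt(1.38), length(nus)))
})

test_that("redistribution only lowers per-class noise in trichromats", {
  tetra <- receptorNoise(buildNamedSystem("USML"))
  for (nm in c("USM", "UML", "USL")) {
    tri <- receptorNoise(buildNamedSystem(nm))
    expect_true(all(tri <= tetra[names(tri)] + 1e-15))
  }
})

test_that("receptors beyond 570 nm honour the requested mechanism", {
  filt <- buildNamedSystem("USML", mech = "filter")
  ops <- buildNamedSystem("USML", mech = "opsin")
  expect_identical(mechanism(receptors(filt)$LWS), "filter-shifted")
  expect_identical(mechanism(receptors(ops)$LWS), "opsin-shifted")
  # classes at or below 570 nm always come straight from the template
  expect_identical(mechanism(receptors(filt)$MWS), "template")
})

test_that("alternative butterfly density presets are available", {
  pap <- densityPreset("papilio")
  expect_equal(unname(pap), c(1, 1, 4.08, 2.92))
  hel <- densityPreset("heliconius")
  expect_equal(unname(hel), c(1, 1.44, 2.22, 11.11))
  sys <- buildNamedSystem("USML", densityFull = pap)
  expect_equal(sum(densities(sys)), sum(pap))
  expect_equal(sys@nu, 0.12 * sqrt(2.92))
})

test_that("visual systems survive a JSON config round trip", {
  for (nm in c("USL", "VS640")) {
    sys <- buildNamedSystem(nm)
    path <- withr::local_tempfile(fileext = ".json")
    writeSystemConfig(sys, path)
    back <- readSystemConfig(path)
    expect_identical(specLabel(back), specLabel(sys))
    expect_equal(densities(back), densities(sys))
    expect_equal(back@nu, sys@nu)
    expect_equal(lapply(receptors(back), intensities),
                 lapply(receptors(sys), intensities), tolerance = 1e-12)
  }
})
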