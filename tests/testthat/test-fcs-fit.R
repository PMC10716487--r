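makeCurve <- function(tau, G, volumes = "central") {
  new("CorrelationCurve", lagsS = tau, G = G, replicates = NULL,
      nChunksUsed = 1L, nChunksTotal = 1L, kind = "auto", volumes = volumes)
}

test_that("noiseless model curves are recovered to numerical precision", {
  tau <- 10^seq(-6, 0, by = 1 / 8)
  g <- fcs3DModel(tau, N = 10, tauDS = 1e-3, k = 4.5, offset = 0.002)
  f <- fitFCS(makeCurve(tau, g), omega0Nm = 276, k = 4.5)
  expect_equal(f@estimates[["N"]], 10, tolerance = 1e-6)
  expect_equal(f@estimates[["tauDS"]], 1e-3, tolerance = 1e-6)
  expect_equal(f@estimates[["offset"]], 0.002, tolerance = 1e-4)

  # 2-component: fractions and both diffusion times, fast ordered first
  g2 <- fcs3DModel2(tau, N = 5, tauDS = 2e-4, tauD2S = 8e-3,
                    fraction = 0.3, k = 4.1)
  f2 <- fitFCS(makeCurve(tau, g2), omega0Nm = 330, k = 4.1, nComponents = 2,
               fixed = c(offset = 0))
  expect_equal(f2@estimates[["tauDS"]], 2e-4, tolerance = 1e-4)
  expect_equal(f2@estimates[["tauD2S"]], 8e-3, tolerance = 1e-4)
  expect_equal(f2@estimates[["fraction"]], 0.3, tolerance = 1e-3)

  # degenerate requests fail loudly
  expect_error(fitFCS(makeCurve(tau[1:2], g[1:2]), omega0Nm = 276, k = 4.5),
               "free parameters")
})

test_that("D follows from tauD and the calibrated waist", {
  tau <- 10^seq(-6, 0, by = 1 / 8)
  g <- fcs3DModel(tau, N = 5, tauDS = 1.076e-3, k = 4.5)
  f <- fitFCS(makeCurve(tau, g), omega0Nm = 276, k = 4.5,
              fixed = c(offset = 0))
  expect_equal(f@D[[1]], 0.276^2 / (4 * 1.076e-3) * 1e-3 * 1e3,
               tolerance = 1e-6)
  expect_equal(f@D[[1]], 17.7, tolerance = 0.01)
})

test_that("circular-scanning model reduces to static at R = 0 and is fit", {
  tau <- 10^seq(-6, -1, by = 1 / 8)
  expect_equal(fcsScanModel(tau, N = 4, tauDS = 1e-3, k = 4.1, offset = 0,
                            omega0Nm = 330, radiusNm = 0, periodUs = 1000),
               fcs3DModel(tau, N = 4, tauDS = 1e-3, k = 4.1))

  # synthetic scan curve: omega0 recovered; deeper dips at doubled R
  g1 <- fcsScanModel(tau, N = 4, tauDS = 1.5e-3, k = 4.1, offset = 0,
                     omega0Nm = 330, radiusNm = 500, periodUs = 1000)
  g2 <- fcsScanModel(tau, N = 4, tauDS = 1.5e-3, k = 4.1, offset = 0,
                     omega0Nm = 330, radiusNm = 1000, periodUs = 1000)
  expect_lt(min(g2), min(g1))
  set.seed(7)
  noisy <- g1 * (1 + rnorm(length(g1), 0, 0.01))
  cal <- calibrateCircularFCS(makeCurve(tau, noisy), radiusNm = 500,
                              periodUs = 1000, k = 4.1)
  expect_equal(cal@estimates[["omega0Nm"]], 330, tolerance = 0.05)
})

test_that("diffusion law classifies motion from the intercept", {
  mkFit <- function(tauDS, waist, se = 1e-5) {
    new("FCSFit", estimates = c(N = 1, tauDS = tauDS, offset = 0),
        se = c(N = 0, tauDS = se, offset = 0), fixed = c(omega0Nm = waist,
                                                         k = 4.1),
        model = "3d", nComponents = 1L, D = (waist * 1e-3)^2 / (4 * tauDS),
        DSe = 0, chisqRed = 1, lagsS = 1, G = 1, fitted = 1,
        volume = "x")
  }
  # exact line through the origin: t0 = 0, free
  ws <- c(276, 330, 390)
  fits <- lapply(ws, function(w) mkFit((w * 1e-3)^2 / (4 * 10), w))
  law <- diffusionLaw(fits)
  expect_equal(law@t0Ms, 0, tolerance = 1e-9)
  expect_identical(law@motionClass, "free")
  expect_equal(law@DLaw, 10, tolerance = 1e-9)

  # positive intercept: hop/domain
  fitsPos <- lapply(ws, function(w)
    mkFit((w * 1e-3)^2 / (4 * 10) + 5e-4, w))
  expect_identical(diffusionLaw(fitsPos)@motionClass, "hop_or_domain")
  # negative intercept: meshwork
  fitsNeg <- lapply(ws, function(w)
    mkFit((w * 1e-3)^2 / (4 * 10) - 5e-4, w))
  expect_identical(diffusionLaw(fitsNeg)@motionClass, "meshwork")
  expect_error(diffusionLaw(fits[1]), "at least 2")
})

test_that("intercepts compatible with zero classify as free motion", {
  # beads-like regression: t0 = -0.03 +/- 0.03 ms has 0 in its CI
  x <- c(0.0762, 0.1089, 0.1521)
  t0 <- -0.03e-3
  fits <- lapply(seq_along(x), function(i) {
    tauD <- x[i] / (4 * 17.7) + t0
    new("FCSFit", estimates = c(N = 1, tauDS = tauD, offset = 0),
        se = c(N = 0, tauDS = 2.1e-5, offset = 0),
        fixed = c(omega0Nm = sqrt(x[i]) * 1e3, k = 4.1), model = "3d",
        nComponents = 1L, D = 17.7, DSe = 0, chisqRed = 1, lagsS = 1,
        G = 1, fitted = 1, volume = "x")
  })
  # perturb points so the OLS residual SE is ~0.03 ms around t0 = -0.03
  fits[[1]]@estimates[["tauDS"]] <- fits[[1]]@estimates[["tauDS"]] + 2.0e-5
  fits[[3]]@estimates[["tauDS"]] <- fits[[3]]@estimates[["tauDS"]] + 1.2e-5
  law <- diffusionLaw(fits)
  expect_lt(abs(law@t0Ms), law@t0SeMs * 1.96)
  expect_identical(law@motionClass, "free")
})

test_that("confinement strength is the central/sum5x5 D ratio", {
  mk <- function(D, DSe) new("FCSFit", estimates = c(N = 1, tauDS = 1e-3,
                                                     offset = 0),
                             se = c(N = 0, tauDS = 0, offset = 0),
                             fixed = c(omega0Nm = 300, k = 4.1),
                             model = "3d", nComponents = 1L, D = D,
                             DSe = DSe, chisqRed = 1, lagsS = 1, G = 1,
                             fitted = 1, volume = "x")
  expect_equal(confinementStrength(mk(1, 0), mk(1, 0))@sConf, 1)
  r <- confinementStrength(mk(2, 0.2), mk(1, 0.1))
  expect_equal(r@sConf, 2)
  expect_equal(r@se, 2 * sqrt(0.01 + 0.01), tolerance = 1e-9)
  expect_error(confinementStrength(mk(-1, 0), mk(1, 0)), "non-positive")
})

test_that("relative cross-correlation amplitudes are amplitude ratios", {
  mk <- function(N) new("FCSFit", estimates = c(N = N, tauDS = 1e-3,
                                                offset = 0),
                        se = c(N = 0, tauDS = 0, offset = 0),
                        fixed = c(omega0Nm = 330, k = 4.1), model = "3d",
                        nComponents = 1L, D = 1, DSe = 0, chisqRed = 1,
                        lagsS = 1, G = 1, fitted = 1, volume = "x")
  # identical split signal: both ratios 1
  r <- relativeCCAmplitude(mk(5), mk(5), mk(5))
  expect_equal(unname(r), c(1, 1))
  # cross amplitude 40% of the autos
  r2 <- relativeCCAmplitude(mk(5), mk(5), mk(12.5))
  expect_equal(unname(r2), c(0.4, 0.4))
  expect_error(relativeCCAmplitude(mk(-2), mk(5), mk(5)), "non-positive")
})

test_that("Stokes-Einstein diameters match the closed form", {
  expect_equal(round(stokesEinsteinDiameter(17.7, 293, 1.0)), 24)
  expect_equal(stokesEinsteinDiameter(4.3, 293, 1.0), 99.8, tolerance = 0.01)
  d1 <- stokesEinsteinDiameter(5, 293, 1)
  expect_equal(stokesEinsteinDiameter(10, 293, 1), d1 / 2)
  expect_error(stokesEinsteinDiameter(-1))
})
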