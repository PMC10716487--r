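test_that("photon correlator matches the brute-force binned correlation", {
  # period-2 binned trace [2,0,2,0,...]: G at one-bin lag is -1
  t <- rep((0:49) * 2000, each = 2) + c(100, 600)   # 2 photons per even us
  s <- tinyStream(rep(12L, length(t)), t, durationS = 1e-4)
  d <- lagDesign(8, tauMinUs = 1, tauMaxS = 2e-5)
  cv <- correlatePhotons(s, design = d)
  oneBin <- which.min(abs(cv@lagsS - 1e-6))
  expect_equal(cv@G[oneBin], -1)

  # random stream: exact agreement with the brute-force oracle at all
  # level-0 lags (same bin width)
  set.seed(11); t2 <- sort(runif(5e4, 0, 1e9))
  s2 <- tinyStream(rep(12L, length(t2)), t2, durationS = 1)
  cv2 <- correlatePhotons(s2, design = lagDesign(8, 1, 0.01))
  lev0 <- which(cv2@lagsS * 1e6 <= 8)
  ks <- round(cv2@lagsS[lev0] * 1e6)
  expect_equal(cv2@G[lev0], bruteForceG(t2, 1e3, 1e6, ks),
               tolerance = 1e-9)

  # coarser levels agree with the oracle at the coarsened bin width
  lag64 <- which.min(abs(cv2@lagsS - 64e-6))
  lev <- floor(log2(cv2@lagsS[lag64] * 1e6 / 8))
  w <- 1e3 * 2^lev
  k <- round(cv2@lagsS[lag64] * 1e9 / w)
  expect_equal(cv2@G[lag64], bruteForceG(t2, w, floor(1e9 / w), k),
               tolerance = 1e-9)
})

test_that("a homogeneous Poisson stream is uncorrelated", {
  s <- poissonStream(2e5, 2, seed = 21)
  cv <- correlatePhotons(s, design = lagDesign(8, 1, 0.1))
  # |G| below 3 standard errors, estimated from the photon counts
  se <- 1 / sqrt(nPhotons(s)) * 3
  expect_true(all(abs(cv@G) < pmax(5 * se, 0.01)))
  expect_lt(mean(abs(cv@G)), 0.005)
})

test_that("autocorrelation amplitude scales as 1/N over a decade", {
  amps <- vapply(c(50L, 160L, 500L), function(n) {
    s <- simulatePhotonStream(emitterSpecies(n = n, D = 10),
                              boxUm = c(5.52, 5.52, 5.52),
                              durationS = 8, seed = 100 + n)
    cv <- chunkedCorrelation(s, chunkS = 2, volume = "sum3x3",
                             design = lagDesign(8, 1, 0.1))
    f <- fitFCS(cv, omega0Nm = 330, k = 4.1, fixed = c(offset = 0))
    1 / f@estimates[["N"]]
  }, 0)
  # amplitudes inversely proportional to the emitter number
  expect_equal(amps[1] / amps[2], 160 / 50, tolerance = 0.2)
  expect_equal(amps[1] / amps[3], 500 / 50, tolerance = 0.2)
})

test_that("autocorrelation is invariant under time reversal", {
  set.seed(5); t <- sort(runif(2e4, 0, 1e8))
  s <- tinyStream(rep(12L, length(t)), t, durationS = 0.1)
  sRev <- tinyStream(rep(12L, length(t)), sort(1e8 - t), durationS = 0.1)
  d <- lagDesign(8, 1, 0.01)
  gF <- correlatePhotons(s, design = d)@G
  gR <- correlatePhotons(sRev, design = d)@G
  # exact at fine lags; coarse multi-tau levels drop a trailing bin when
  # the halved trace length is odd, so only near-equality holds there
  lagsS <- correlatePhotons(s, design = d)@lagsS
  fine <- lagsS < 5e-4
  expect_equal(gF[fine], gR[fine], tolerance = 1e-9)
  expect_equal(gF, gR, tolerance = 0.05)
})

test_that("chunking averages good chunks and rejects artifacts", {
  s <- poissonStream(1e5, 60, seed = 31)
  cv <- chunkedCorrelation(s, chunkS = 10)
  expect_identical(cv@nChunksTotal, 6L)
  expect_identical(cv@nChunksUsed, 6L)
  # average lies within the replicate scatter
  scatter <- apply(cv@replicates, 1, sd)
  expect_true(all(abs(cv@G - rowMeans(cv@replicates)) <= 1e-12))
  expect_true(mean(abs(cv@G)) < mean(scatter))

  # a 10x intensity step in one chunk is rejected
  set.seed(32)
  extra <- sort(runif(9e5, 20e9, 30e9))     # chunk 3 made 10x brighter
  t2 <- sort(c(absTimes(s), extra))
  s2 <- tinyStream(rep(12L, length(t2)), t2, durationS = 60)
  cv2 <- chunkedCorrelation(s2, chunkS = 10)
  expect_identical(cv2@nChunksUsed, 5L)

  # all chunks artifactual -> explicit error with a QC report
  expect_error(
    chunkedCorrelation(tinyStream(rep(12L, 3), c(1e9, 2e9, 21e9),
                                  durationS = 60), chunkS = 10),
    "rejected|mean intensity")

  # too short for 2 chunks -> precondition error
  s3 <- poissonStream(1e5, 5, seed = 33)
  expect_error(chunkedCorrelation(s3, chunkS = 10), "fewer than 2 chunks")
})

test_that("cross-correlation reports co-diffusion", {
  # identical stream on both inputs equals the autocorrelation
  s <- poissonStream(1e5, 2, seed = 41)
  m <- mergeChannels(s, "central")
  d <- lagDesign(8, 1, 0.01)
  cx <- crossColorCorrelation(m, m, design = d)
  expect_identical(cx@kind, "cross")
  expect_equal(cx@G, correlatePhotons(m, design = d)@G)

  # independent species: amplitude ~ 0; bound fraction raises it
  # monotonically towards the split-signal limit
  amps <- vapply(c(0, 0.5, 1), function(f) {
    s2 <- simulateDualColor(n = 200, coDiffusingFraction = f,
                            boxUm = c(5.52, 5.52, 5.52),
                            durationS = 6, seed = round(50 + 10 * f))
    g <- mergeChannels(s2, "sum3x3"); r <- mergeChannels(s2, "single_element")
    cv <- crossColorCorrelation(g, r, design = lagDesign(8, 1, 0.1))
    fit <- fitFCS(cv, omega0Nm = 330, k = 4.1, fixed = c(offset = 0))
    1 / fit@estimates[["N"]]
  }, 0)
  auto <- {
    s2 <- simulateDualColor(n = 200, coDiffusingFraction = 1,
                            boxUm = c(5.52, 5.52, 5.52),
                            durationS = 6, seed = 60)
    cv <- chunkedCorrelation(s2, chunkS = 2, volume = "sum3x3",
                             design = lagDesign(8, 1, 0.1))
    f <- fitFCS(cv, omega0Nm = 330, k = 4.1, fixed = c(offset = 0))
    1 / f@estimates[["N"]]
  }
  expect_lt(amps[1], 0.1 * auto)
  expect_gt(amps[2], amps[1]); expect_lt(amps[2], amps[3])
  expect_equal(amps[2] / auto, 0.5, tolerance = 0.25)

  expect_error(correlatePhotons(PhotonStream()), "empty")
})
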