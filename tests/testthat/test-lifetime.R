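expStream <- function(n, tauNs, seed = 1, irfSigma = 0, irfOffset = 0,
                      repPeriodNs = 25) {
  set.seed(seed)
  m <- rexp(n, 1 / tauNs) + irfOffset + rnorm(n, 0, irfSigma)
  tinyStream(rep(12L, n), seq_len(n) * 1e3,
             microtimeNs = m %% repPeriodNs,
             laser = LaserConfig(repPeriodNs = repPeriodNs,
                                 irfSigmaNs = irfSigma,
                                 irfOffsetNs = irfOffset))
}

test_that("decay histograms conserve counts and match analytic bins", {
  # all microtimes equal: a single occupied bin
  s <- tinyStream(rep(12L, 4), 1:4, microtimeNs = rep(7.3, 4))
  h <- decayHistogram(s, nBins = 64)
  expect_identical(sum(h@counts > 0), 1L)
  expect_equal(sum(h@counts), 4)

  # large exponential sample: per-bin contents within Poisson bounds of
  # the analytic bin integrals (folding included)
  n <- 1e6; tau <- 2.5; Trep <- 25
  s2 <- expStream(n, tau, seed = 2)
  h2 <- decayHistogram(s2, nBins = 64)
  e <- h2@binEdgesNs
  # folded exponential: sum over wrap-around periods
  pBin <- (exp(-e[-length(e)] / tau) - exp(-e[-1] / tau)) /
    (1 - exp(-Trep / tau))
  expected <- n * pBin
  z <- (h2@counts - expected) / sqrt(expected)
  expect_lt(max(abs(z)), 5)
  expect_equal(sum(h2@counts), n)

  # channel homogeneity in a uniform simulation: chi-square across the
  # 25 array elements on a coarse decay histogram
  sim <- simulatePhotonStream(emitterSpecies(n = 200, brightnessCps = 2e5),
                              durationS = 3, seed = 5)
  sim <- foldMicrotime(sim)
  byCh <- lapply(0:24, function(ch) {
    sel <- channels(sim) == ch
    tabulate(pmin(8, floor(microtimes(sim)[sel] / 25 * 8) + 1), 8)
  })
  counts <- do.call(rbind, byCh)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 1e-4)

  expect_error(decayHistogram(tinyStream(12L, 1)), "no microtimes")
})

test_that("mono-exponential tail fits recover the lifetime", {
  # exact exponential histogram: noiseless recovery
  edges <- seq(0, 25, length.out = 257)
  tc <- (edges[-1] + edges[-257]) / 2
  hExact <- new("DecayHistogram", binEdgesNs = edges,
                counts = 1e5 * exp(-tc / 1.0), source = "x",
                repPeriodNs = 25)
  f <- fitMonoexp(hExact)
  expect_equal(f@tauNs, 1.0, tolerance = 1e-6)

  # beads-regime decay with IRF: recovery within 0.1 ns
  s <- expStream(1e5, 1.3, seed = 3, irfSigma = 0.1, irfOffset = 2)
  f2 <- fitMonoexp(decayHistogram(s, nBins = 256))
  expect_equal(f2@tauNs, 1.3, tolerance = 0.1 / 1.3)

  # eGFP-regime lifetime recovered within 2%
  s3 <- expStream(5e5, 2.55, seed = 4, irfSigma = 0.1, irfOffset = 2)
  f3 <- fitMonoexp(decayHistogram(s3, nBins = 256))
  expect_equal(f3@tauNs, 2.55, tolerance = 0.02)

  expect_error(fitMonoexp(hExact, windowNs = c(24.7, 25)), "fewer than 5")
})

test_that("phasors follow the closed form and the universal circle", {
  # tau -> 0: (g, s) -> (1, 0)
  h0 <- expStream(2e5, 0.01, seed = 6)
  p0 <- phasor(decayHistogram(h0, nBins = 256))
  expect_equal(p0@g, 1, tolerance = 1e-3)
  expect_equal(p0@s, 0, tolerance = 0.05)

  # tau = 2.5 ns at T_rep = 12.5 ns: closed-form g, s
  th <- phasorTheory(2.5, 12.5)
  expect_equal(th[["g"]], 0.3877, tolerance = 1e-3)
  expect_equal(th[["s"]], 0.4872, tolerance = 1e-3)
  s <- expStream(1e6, 2.5, seed = 7, repPeriodNs = 12.5)
  p <- phasor(s)
  expect_equal(p@g, th[["g"]], tolerance = 0.01)
  expect_equal(p@s, th[["s"]], tolerance = 0.01)
  # mono-exponential point sits on the universal circle g^2 + s^2 = g
  expect_equal(p@g^2 + p@s^2, p@g, tolerance = 5e-3)

  # histogram route agrees with the photon route to discretization accuracy
  ph <- phasor(decayHistogram(foldMicrotime(s), nBins = 256))
  expect_equal(ph@g, p@g, tolerance = 1e-3)
  expect_equal(ph@s, p@s, tolerance = 1e-3)

  # two-component mixtures lie on the chord between the pure phasors
  pa <- phasorTheory(1.0, 12.5); pb <- phasorTheory(4.0, 12.5)
  set.seed(8)
  mix <- c(rexp(6e5, 1), rexp(4e5, 1 / 4)) %% 12.5
  sMix <- tinyStream(rep(12L, 1e6), seq_len(1e6), microtimeNs = mix,
                     laser = LaserConfig(repPeriodNs = 12.5))
  pm <- phasor(sMix)
  # collinearity: cross product of (pm - pa) and (pb - pa) vanishes
  cross <- (pm@g - pa[["g"]]) * (pb[["s"]] - pa[["s"]]) -
    (pm@s - pa[["s"]]) * (pb[["g"]] - pa[["g"]])
  expect_lt(abs(cross), 5e-3)
  # strictly inside the universal circle
  expect_lt(pm@g^2 + pm@s^2, pm@g)
})

test_that("tail fit and phasor lifetimes agree on clean decays", {
  s <- expStream(5e5, 2.0, seed = 9)
  h <- decayHistogram(s, nBins = 256)
  tauFit <- fitMonoexp(h)@tauNs
  tauPh <- phasorLifetime(phasor(h))
  expect_equal(tauPh, tauFit, tolerance = 0.05)
})

test_that("phasor calibration maps the reference onto the circle", {
  # measured equals theoretical: identity calibration
  th <- phasorTheory(1.0, 25)
  ref <- new("PhasorSet", g = th[["g"]], s = th[["s"]], counts = 1e5,
             harmonic = 1L, omega = 2 * pi / 25, calibrated = FALSE,
             imageDim = integer(0), pixelIndex = integer(0))
  cal <- calibratePhasor(ref, 1.0)
  expect_equal(cal@rotation, 0, tolerance = 1e-12)
  expect_equal(cal@scale, 1, tolerance = 1e-12)

  # an IRF delay rotates the phasor off the circle; calibration with a
  # 1 ns dye puts a 3.9 ns dye back on the circle
  mRef <- phasor(expStream(5e5, 1.0, seed = 10, irfOffset = 1))
  cal2 <- calibratePhasor(mRef, 1.0)
  sample <- phasor(expStream(5e5, 3.9, seed = 11, irfOffset = 1))
  calSample <- applyPhasorCalibration(sample, cal2)
  expect_equal(calSample@g^2 + calSample@s^2, calSample@g,
               tolerance = 5e-3)
  expect_equal(phasorLifetime(calSample), 3.9, tolerance = 0.05)

  # provenance guard: calibrating twice is refused
  expect_error(applyPhasorCalibration(calSample, cal2), "already calibrated")
  degen <- new("PhasorSet", g = 0, s = 0, counts = 1e5, harmonic = 1L,
               omega = 2 * pi / 25, calibrated = FALSE,
               imageDim = integer(0), pixelIndex = integer(0))
  expect_error(calibratePhasor(degen, 1), "degenerate")
})

test_that("centroid segmentation separates a two-lifetime phantom", {
  # discs with shorter lifetime on a longer-lifetime background
  n <- 48
  mkDiscs <- function(r) {
    m <- matrix(FALSE, n, n)
    for (cc in list(c(14, 14), c(34, 30)))
      m <- m | outer(seq_len(n), seq_len(n), function(y, x)
        (y - cc[1])^2 + (x - cc[2])^2 <= r^2)
    m
  }
  disc <- mkDiscs(8)
  bg <- matrix(3e5, n, n) * !disc
  fg <- matrix(3e5, n, n) * disc
  s <- simulateRasterScan(list(
    list(brightness = bg, lifetimeNs = 2.6),
    list(brightness = fg, lifetimeNs = 1.4)),
    pixelSizeNm = 80, dwellUs = 40,
    laser = LaserConfig(irfOffsetNs = 0, irfSigmaNs = 0.05), seed = 12)
  stack <- buildStack(s, microtimeBins = 64)
  ph <- phasor(stack, threshold = 0.1)
  seg <- phasorSegment(ph)
  expect_false(seg$degenerate)
  # short-lifetime label (2) should coincide with the discs; judged on
  # core regions 2 px away from the boundary (edge pixels mix lifetimes
  # through the PSF)
  core <- mkDiscs(6); bgCore <- !mkDiscs(10)
  acc <- (sum(seg$mask[core] == 2) + sum(seg$mask[bgCore] == 1)) /
    (sum(core) + sum(bgCore))
  expect_gt(acc, 0.95)

  # uniform lifetime: degenerate split flagged, single label
  s1 <- simulateRasterScan(list(brightness = matrix(1e5, 24, 24),
                                lifetimeNs = 2.5),
                           pixelSizeNm = 80, dwellUs = 40, seed = 13)
  ph1 <- phasor(buildStack(s1, microtimeBins = 64))
  seg1 <- phasorSegment(ph1)
  if (!seg1$degenerate)      # noise keeps it non-degenerate: still one side
    expect_true(all(seg1$mask[seg1$mask > 0] %in% c(1L, 2L)))

  # 100% threshold leaves no pixels
  expect_error(phasor(buildStack(s1, microtimeBins = 64), threshold = 1),
               "threshold")
})
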