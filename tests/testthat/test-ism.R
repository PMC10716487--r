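test_that("the 4D stack assigns photons to voxels and conserves counts", {
  # single photon: exactly one nonzero voxel
  scan <- ScanMetadata("raster", pixelDwellUs = 10, nX = 8, nY = 6,
                       pixelSizeNm = 50)
  s <- tinyStream(7L, 4L * 8L + 3L + 0.5, microtimeNs = 3,
                  durationS = 48 * 10e-6, scan = scan)
  s@tAbsNs <- (4 * 8 + 3) * 1e4 + 500   # pixel (y = 4, x = 3)
  st <- buildStack(s, microtimeBins = 4)
  expect_equal(sum(st@counts), 1)
  expect_equal(which(st@counts > 0, arr.ind = TRUE)[1, ],
               c(dim1 = 5, dim2 = 4, dim3 = 8, dim4 = 1))

  # integrating microtimes equals intensity-mode imaging
  stk <- beadStack(seed = 2, microtimeBins = 16)
  stk1 <- beadStack(seed = 2, microtimeBins = 1)
  expect_equal(apply(stk@counts, 1:3, sum), array(stk1@counts,
                                                  dim(stk1@counts)[1:3]))

  # photons beyond the declared frame: clock inconsistency diagnostics
  bad <- tinyStream(3L, 1e9, durationS = 2, scan = scan)
  expect_error(buildStack(bad), "clock inconsistency: 1 photons")
})

test_that("phase-correlation registration recovers constructed shifts", {
  stk <- beadStack(seed = 3)
  imgs <- apply(stk@counts, c(1, 2, 3), sum)
  base <- imgs[, , 13]
  shifted <- array(0, dim = dim(imgs))
  truth <- matrix(0, 25, 2)
  set.seed(4)
  for (ch in 1:25) {
    dy <- sample(-3:3, 1); dx <- sample(-3:3, 1)
    if (ch == 13) { dy <- 0; dx <- 0 }
    truth[ch, ] <- c(dy, dx)
    src <- base
    out <- matrix(0, nrow(base), ncol(base))
    ys <- seq_len(nrow(base)) - dy; xs <- seq_len(ncol(base)) - dx
    ok <- ys >= 1 & ys <= nrow(base); okx <- xs >= 1 & xs <= ncol(base)
    out[ok, okx] <- src[ys[ok], xs[okx]]
    shifted[, , ch] <- out
  }
  stk2 <- stk
  stk2@counts <- array(shifted, dim = c(dim(imgs), 1))
  fp <- registerChannels(stk2)
  expect_equal(unname(fp@shifts), truth, tolerance = 1e-6)

  # all channels identical -> all shifts zero
  same <- stk
  same@counts <- array(rep(base, 25), dim = c(dim(base), 25, 1))
  fp0 <- registerChannels(same)
  expect_true(all(abs(fp0@shifts) < 1e-9))

  # inverse consistency: swapping roles negates the shift
  a <- base
  b <- shifted[, , 1]
  pcAB <- photonFFS:::.phaseCorrelate(a, b)$shift
  pcBA <- photonFFS:::.phaseCorrelate(b, a)$shift
  expect_equal(pcAB, -pcBA, tolerance = 0.1)
})

test_that("registration on simulated frames matches the half-pitch pattern", {
  stk <- beadStack(seed = 5)
  fp <- registerChannels(stk)
  halfPitchPx <- DetectorGeometry()@pitchSampleNm / 2 / 40
  good <- which(!fp@lowConfidence)
  for (ch in intersect(c(8, 12, 14, 18), good)) {   # inner ring, 1-based
    row <- (ch - 1) %/% 5; col <- (ch - 1) %% 5
    expect_equal(unname(fp@shifts[ch, ]),
                 c((row - 2) * halfPitchPx, (col - 2) * halfPitchPx),
                 tolerance = 0.35)
  }
})

test_that("pixel reassignment narrows the bead image by the ISM factor", {
  stk <- beadStack(seed = 6)
  fp <- registerChannels(stk)
  ism <- reconstructISM(stk, fp)
  open <- reconstructISM(stk, new("ShiftFingerprint",
                                  shifts = matrix(0, 25, 2),
                                  confidence = rep(1, 25),
                                  lowConfidence = rep(FALSE, 25)))
  # zero fingerprint reproduces the plain channel sum
  expect_equal(open@intensity,
               apply(stk@counts, c(1, 2), sum), tolerance = 1e-9)
  ratio <- imageFWHM(open@intensity) / imageFWHM(ism@intensity)
  expect_gt(ratio, 1.2); expect_lt(ratio, 1.5)

  # photon conservation for integer shifts, up to the cropped border
  fpInt <- fp; fpInt@shifts <- round(fp@shifts)
  ismInt <- reconstructISM(stk, fpInt)
  crop <- ismInt@cropPx
  d <- dim(stk@counts)
  inFrame <- sum(ismInt@intensity)
  total <- sum(stk@counts)
  expect_gt(inFrame / total, 0.95)   # bead centred: little lost at borders
  # sub-pixel interpolation leaks less than 0.5%
  expect_gt(sum(ism@intensity) / total, 0.95)

  expect_error(reconstructISM(stk, new("ShiftFingerprint",
                                       shifts = matrix(0, 9, 2),
                                       confidence = rep(1, 9),
                                       lowConfidence = rep(FALSE, 9))),
               "channels")
})

test_that("FLISM lifetime maps recover phantom lifetimes", {
  n <- 40
  disc <- outer(seq_len(n), seq_len(n), function(y, x)
    (y - 20)^2 + (x - 20)^2 <= 64)
  s <- simulateRasterScan(list(
    list(brightness = matrix(1e5, n, n) * !disc, lifetimeNs = 2.6),
    list(brightness = matrix(2e5, n, n) * disc, lifetimeNs = 2.0)),
    pixelSizeNm = 80, dwellUs = 60,
    laser = LaserConfig(irfOffsetNs = 0, irfSigmaNs = 0.05), seed = 7)
  stk <- buildStack(s, microtimeBins = 64)
  fp <- registerChannels(stk)
  ism <- reconstructISM(stk, fp, lifetime = "phasor", minCounts = 100)
  tauIn <- median(ism@lifetimeMapNs[disc[(fp2 <- ism@cropPx) +
    seq_len(n - 2 * fp2), fp2 + seq_len(n - 2 * fp2)]], na.rm = TRUE)
  tauOut <- median(ism@lifetimeMapNs[!disc[fp2 + seq_len(n - 2 * fp2),
                                           fp2 + seq_len(n - 2 * fp2)]],
                   na.rm = TRUE)
  expect_equal(tauIn, 2.0, tolerance = 0.05)
  expect_equal(tauOut, 2.6, tolerance = 0.05)

  # single-lifetime phantom: pixel lifetimes within 5% wherever counts
  # are sufficient, via both phasor and tail-fit routes
  s1 <- simulateRasterScan(list(brightness = matrix(2e5, 20, 20),
                                lifetimeNs = 2.5),
                           pixelSizeNm = 80, dwellUs = 60,
                           laser = LaserConfig(irfOffsetNs = 0,
                                               irfSigmaNs = 0.05), seed = 8)
  stk1 <- buildStack(s1, microtimeBins = 64)
  fp1 <- registerChannels(stk1)
  ismP <- reconstructISM(stk1, fp1, lifetime = "phasor", minCounts = 100)
  expect_lt(max(abs(ismP@lifetimeMapNs / 2.5 - 1), na.rm = TRUE), 0.05)
  ismF <- reconstructISM(stk1, fp1, lifetime = "fit", minCounts = 100)
  inner <- ismF@lifetimeMapNs[5:12, 5:12]
  expect_lt(median(abs(inner / 2.5 - 1), na.rm = TRUE), 0.05)
})
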