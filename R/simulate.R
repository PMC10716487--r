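#' Emitter species definition
#'
#' Describes one fluorescent species in the simulation box: emitter count,
#' diffusion coefficient, peak molecular brightness at the detection-volume
#' centre, mono-exponential fluorescence lifetime and detection color
#' (`"green"` = SPAD array, `"red"` = single-element detector, `"both"` =
#' a dual-labeled, co-diffusing species emitting in both colors).
#'
#' @param n number of emitters in the box (the default gives ~3 emitters
#'   per um^3, i.e. ~1.6 in the central detection volume, in the default
#'   simulation box).
#' @param D diffusion coefficient (um^2/s).
#' @param brightnessCps peak photon rate per emitter (counts/s).
#' @param lifetimeNs fluorescence lifetime tau_F (ns); must be below the
#'   laser repetition period.
#' @param color `"green"`, `"red"` or `"both"`.
#' @param motion a [motionModel()].
#' @return A list of class `"emitterSpecies"`.
#' @export
emitterSpecies <- function(n = 4000L, D = 10, brightnessCps = 1e5,
                           lifetimeNs = 2.5,
                           color = c("green", "red", "both"),
                           motion = motionModel("free")) {
  color <- match.arg(color)
  stopifnot(n >= 0, D >= 0, brightnessCps >= 0, lifetimeNs > 0)
  structure(list(n = as.integer(n), D = D, brightnessCps = brightnessCps,
                 lifetimeNs = lifetimeNs, color = color, motion = motion),
            class = "emitterSpecies")
}

#' Motion model for simulated emitters
#'
#' Free Brownian motion, transient trapping in reflective spherical domains
#' (domain-confined diffusion: positive diffusion-law intercept, S_conf < 1),
#' or hopping through a cubic meshwork of permeable barriers.
#'
#' @param kind `"free"`, `"trap"` or `"hop"`.
#' @param domainRadiusNm trap-domain radius (nm).
#' @param trapRateS,escapeRateS trapping and escape rates (1/s).
#' @param dIn diffusion coefficient inside a domain (um^2/s).
#' @param meshSizeNm meshwork cell size (nm).
#' @param hopProbability barrier-crossing acceptance probability in `[0,1]`.
#' @return A list of class `"motionModel"` (fields in simulator units).
#' @export
motionModel <- function(kind = c("free", "trap", "hop"),
                        domainRadiusNm = 100, trapRateS = 50,
                        escapeRateS = 10, dIn = 0.5,
                        meshSizeNm = 200, hopProbability = 0.1) {
  kind <- match.arg(kind)
  stopifnot(hopProbability >= 0, hopProbability <= 1,
            trapRateS >= 0, escapeRateS >= 0)
  structure(list(kind = match(kind, c("free", "trap", "hop")) - 1L,
                 domain_radius_um = domainRadiusNm * 1e-3,
                 trap_rate_s = trapRateS, escape_rate_s = escapeRateS,
                 d_in = dIn, mesh_size_um = meshSizeNm * 1e-3,
                 hop_prob = hopProbability, kindName = kind),
            class = "motionModel")
}

.checkDt <- function(dtUs, species, geometry) {
  wMin <- min(geometry@waists) * 1e-3  # um
  for (sp in species) {
    Dmax <- max(sp$D, if (sp$motion$kindName == "trap") sp$motion$d_in else 0)
    step <- sqrt(2 * Dmax * dtUs * 1e-6)
    if (step >= wMin / 5)
      stop(sprintf(paste0("dt too coarse for D = %g um^2/s: rms step %.1f nm ",
                          "exceeds omega0/5 = %.1f nm"),
                   Dmax, step * 1e3, wMin / 5 * 1e3))
  }
  invisible(TRUE)
}

.speciesForCpp <- function(sp) {
  list(n = sp$n, D = sp$D, brightness_cps = sp$brightnessCps,
       lifetime_ns = sp$lifetimeNs,
       color = match(sp$color, c("green", "red", "both")) - 1L,
       motion = sp$motion[c("kind", "domain_radius_um", "trap_rate_s",
                            "escape_rate_s", "d_in", "mesh_size_um",
                            "hop_prob")])
}

.waistVec <- function(geometry) {
  geometry@waists[c("central", "sum3x3", "sum5x5", "single_element")]
}
.eccVec <- function(geometry) {
  geometry@eccentricities[c("central", "sum3x3", "sum5x5", "single_element")]
}

#' Simulate a photon stream from diffusing emitters
#'
#' Brownian-dynamics simulation of point emitters in a periodic box centred
#' on the detection volume, with Poisson photon emission from 3D-Gaussian
#' detection volumes and TCSPC microtimes drawn from the species lifetime
#' convolved with a Gaussian IRF and folded by the laser period.
#'
#' Green photons are distributed over the SPAD array channels such that
#' merging channels ([mergeChannels()]) reproduces each calibrated nested
#' detection volume (central / sum 3x3 / sum 5x5) exactly as a 3D Gaussian
#' with its calibrated waist; red photons are detected by the single-element
#' detector (channel 25). With `scan`, the detection-volume centre follows a
#' circular trajectory (circular-scanning FCS).
#'
#' @param species list of [emitterSpecies()] (or a single one).
#' @param boxUm simulation box dimensions (um), periodic boundaries. The
#'   default is 40x the central waist per axis: in a periodic box the
#'   slowest surviving concentration mode decays at `D (2 pi / L)^2`, and
#'   a box this size keeps the resulting suppression of the correlation
#'   tail (and hence the diffusion-law intercept bias) an order of
#'   magnitude below the statistical noise of a 60-s measurement. Smaller
#'   boxes (>= 20x the waist) remain valid for amplitude- or
#'   lifetime-oriented runs.
#' @param dtUs time step (us); must satisfy `sqrt(2 D dt) < omega0/5`.
#' @param durationS acquisition length (s).
#' @param geometry,laser acquisition configuration.
#' @param scan `NULL` (point measurement) or a circular-scan
#'   [ScanMetadata-class].
#' @param seed integer seed; the same configuration and seed reproduce the
#'   stream exactly.
#' @param coarseFarSteps let freely diffusing emitters far outside the
#'   detection region take aggregated Brownian steps (statistically exact
#'   for free motion; substantial speed-up).
#' @return A [PhotonStream-class] (absolute times quantized to 1 ns,
#'   microtimes to 1 ps, matching the on-disk format resolution).
#' @examples
#' s <- simulatePhotonStream(durationS = 0.2, seed = 7)
#' s
#' @export
simulatePhotonStream <- function(species = emitterSpecies(),
                                 boxUm = c(11.04, 11.04, 11.04), dtUs = 10,
                                 durationS = 10,
                                 geometry = DetectorGeometry(),
                                 laser = LaserConfig(), scan = NULL,
                                 seed = 1, coarseFarSteps = TRUE) {
  if (is(species, "emitterSpecies")) species <- list(species)
  stopifnot(length(boxUm) == 3, dtUs > 0, durationS > 0)
  .checkDt(dtUs, species, geometry)
  for (sp in species)
    if (sp$lifetimeNs >= laser@repPeriodNs)
      stop("species lifetime must be below the laser repetition period")
  scanMode <- 0L; scanR <- 0; scanT <- 1
  if (!is.null(scan)) {
    if (scan@mode != "circular")
      stop("simulatePhotonStream supports point or circular scans; ",
           "use simulateRasterScan for raster imaging")
    scanMode <- 1L; scanR <- scan@radiusNm; scanT <- scan@periodUs
  }
  raw <- cpp_simulate_stream(lapply(species, .speciesForCpp),
                             boxUm[1], boxUm[2], boxUm[3], dtUs, durationS,
                             .waistVec(geometry), .eccVec(geometry),
                             laser@repPeriodNs, laser@irfSigmaNs,
                             laser@irfOffsetNs, scanMode, scanR, scanT,
                             as.numeric(seed), isTRUE(coarseFarSteps))
  PhotonStream(channel = raw$channel, tAbsNs = round(raw$t_ns),
               microtimeNs = round(raw$microtime_ns * 1e3) / 1e3,
               geometry = geometry, laser = laser, scan = scan,
               durationS = durationS)
}

#' Simulate emitter trajectories
#'
#' Explicit Brownian/trap/hop trajectories in a periodic box, for use with
#' [emitPhotons()] and for motion-model diagnostics (e.g. mean-square
#' displacement).
#'
#' @inheritParams simulatePhotonStream
#' @param nEmitters number of emitters.
#' @param D diffusion coefficient (um^2/s).
#' @param motion a [motionModel()].
#' @param nSteps number of time steps.
#' @param stride record every `stride`-th position.
#' @return Array of dimensions (timepoints, emitters, xyz) in um, with
#'   attributes `dtUs` (sampling interval `stride * dtUs`) and `boxUm`.
#' @export
simulateTrajectories <- function(nEmitters = 10L, D = 10,
                                 motion = motionModel("free"),
                                 boxUm = c(11.04, 11.04, 11.04), dtUs = 10,
                                 nSteps = 1000L, stride = 1L, seed = 1) {
  .checkDt(dtUs, list(list(D = D, motion = motion)),
           DetectorGeometry())
  pos <- cpp_simulate_trajectories(
    as.integer(nEmitters), D,
    motion[c("kind", "domain_radius_um", "trap_rate_s", "escape_rate_s",
             "d_in", "mesh_size_um", "hop_prob")],
    boxUm[1], boxUm[2], boxUm[3], dtUs, as.integer(nSteps),
    as.integer(stride), as.numeric(seed))
  attr(pos, "dtUs") <- dtUs * stride
  attr(pos, "boxUm") <- boxUm
  pos
}

#' Emit photons from explicit trajectories
#'
#' Applies the detection and microtime model of [simulatePhotonStream()]
#' to a recorded trajectory array (positions relative to the detection
#' volume centre at the origin).
#'
#' @param trajectories array from [simulateTrajectories()] with
#'   `stride = 1`.
#' @param brightnessCps,lifetimeNs,color species emission parameters.
#' @inheritParams simulatePhotonStream
#' @return A [PhotonStream-class].
#' @export
emitPhotons <- function(trajectories, brightnessCps = 1e5, lifetimeNs = 2.5,
                        color = c("green", "red", "both"),
                        geometry = DetectorGeometry(), laser = LaserConfig(),
                        seed = 1) {
  color <- match.arg(color)
  dtUs <- attr(trajectories, "dtUs")
  if (is.null(dtUs)) stop("trajectories must carry a dtUs attribute")
  raw <- cpp_emit_photons(trajectories, dtUs, .waistVec(geometry),
                          .eccVec(geometry), brightnessCps, lifetimeNs,
                          match(color, c("green", "red", "both")) - 1L,
                          laser@repPeriodNs, laser@irfSigmaNs,
                          laser@irfOffsetNs, as.numeric(seed))
  # emission covers every recorded position, i.e. dim[1] steps
  PhotonStream(channel = raw$channel, tAbsNs = round(raw$t_ns),
               microtimeNs = round(raw$microtime_ns * 1e3) / 1e3,
               geometry = geometry, laser = laser,
               durationS = dim(trajectories)[1] * dtUs * 1e-6)
}

#' Simulate a dual-color measurement with a tunable co-diffusing fraction
#'
#' Builds a green species (SPAD array), a red species (single-element
#' detector) and a dual-labeled species sharing one trajectory and emitting
#' in both colors, such that each color sees `n` emitters of which
#' `round(coDiffusingFraction * n)` are bound pairs.
#'
#' @param n emitters per color.
#' @param coDiffusingFraction fraction of bound (co-diffusing) pairs in
#'   `[0, 1]`.
#' @param D,brightnessCps,lifetimeGreenNs,lifetimeRedNs species parameters.
#' @inheritParams simulatePhotonStream
#' @return A [PhotonStream-class] containing both colors (array channels
#'   0-24 = green, channel 25 = red).
#' @export
simulateDualColor <- function(n = 3200L, coDiffusingFraction = 0, D = 10,
                              brightnessCps = 1e5, lifetimeGreenNs = 2.5,
                              lifetimeRedNs = 3.5,
                              boxUm = c(11.04, 11.04, 11.04), dtUs = 10,
                              durationS = 10, geometry = DetectorGeometry(),
                              laser = LaserConfig(), seed = 1) {
  stopifnot(coDiffusingFraction >= 0, coDiffusingFraction <= 1)
  nBoth <- as.integer(round(coDiffusingFraction * n))
  nOnly <- as.integer(n) - nBoth
  species <- list()
  if (nOnly > 0) {
    species <- c(species,
      list(emitterSpecies(nOnly, D, brightnessCps, lifetimeGreenNs, "green"),
           emitterSpecies(nOnly, D, brightnessCps, lifetimeRedNs, "red")))
  }
  if (nBoth > 0)
    species <- c(species,
      list(emitterSpecies(nBoth, D, brightnessCps, lifetimeGreenNs, "both")))
  simulatePhotonStream(species, boxUm = boxUm, dtUs = dtUs,
                       durationS = durationS, geometry = geometry,
                       laser = laser, seed = seed)
}

# Evaluate expr with a local, restorable RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# 2D convolution via FFT (zero padding, 'same' output size).
.conv2 <- function(img, kernel) {
  ni <- dim(img); nk <- dim(kernel)
  np <- ni + nk - 1L
  pi2 <- matrix(0, np[1], np[2]); pi2[1:ni[1], 1:ni[2]] <- img
  pk <- matrix(0, np[1], np[2]); pk[1:nk[1], 1:nk[2]] <- kernel
  full <- Re(stats::fft(stats::fft(pi2) * stats::fft(pk), inverse = TRUE)) /
    prod(np)
  off <- (nk - 1L) %/% 2L
  full[off[1] + 1:ni[1], off[2] + 1:ni[2]]
}

#' Simulate a raster-scanned frame of a static phantom
#'
#' The detection-volume centre raster-scans a static object. Each SPAD
#' element sees the object convolved with its effective point-spread
#' function: the product of the excitation Gaussian and the element's
#' laterally offset detection Gaussian, i.e. a narrowed Gaussian
#' (`omega_eff = omega / sqrt(2)` for equal widths) displaced by half the
#' projected element offset -- the property adaptive pixel reassignment
#' exploits. Per-pixel, per-element photon counts are Poisson; microtimes
#' follow each phantom component's lifetime convolved with the IRF.
#'
#' @param components list of phantom components, each a list with
#'   `brightness` (matrix, counts/s at focus, dimensions (y, x)) and
#'   `lifetimeNs` (scalar).
#' @param pixelSizeNm raster pixel size (nm).
#' @param dwellUs pixel dwell time (us).
#' @param excWaistNm excitation/detection single-path waist (nm); default
#'   `sqrt(2)` times the calibrated central-volume waist, so the central
#'   element's effective PSF has the calibrated width.
#' @inheritParams simulatePhotonStream
#' @return A [PhotonStream-class] with raster [ScanMetadata-class]; photons
#'   are assigned to pixels through the pixel dwell clock.
#' @export
simulateRasterScan <- function(components, pixelSizeNm = 50, dwellUs = 100,
                               geometry = DetectorGeometry(),
                               laser = LaserConfig(), excWaistNm = NULL,
                               seed = 1) {
  if (!is.null(components$brightness)) components <- list(components)
  dims <- dim(components[[1]]$brightness)
  nY <- dims[1]; nX <- dims[2]
  if (is.null(excWaistNm))
    excWaistNm <- sqrt(2) * geometry@waists[["central"]]
  wEffNm <- excWaistNm / sqrt(2)     # product of two equal Gaussians
  sigmaPx <- (wEffNm / 2) / pixelSizeNm
  nr <- geometry@nRows; nc <- geometry@nCols
  nCh <- nr * nc
  dwellNs <- dwellUs * 1e3

  .withSeed(seed, {
    chan <- integer(0); tAbs <- numeric(0); micro <- numeric(0)
    kHalf <- ceiling(4 * sigmaPx + nr * geometry@pitchSampleNm / pixelSizeNm)
    kIdx <- -kHalf:kHalf
    for (comp in components) {
      rates <- comp$brightness
      for (ch in 0:(nCh - 1L)) {
        row <- ch %/% nc; col <- ch %% nc
        # projected element offset and resulting image displacement (half)
        sxNm <- (col - (nc - 1) / 2) * geometry@pitchSampleNm
        syNm <- (row - (nr - 1) / 2) * geometry@pitchSampleNm
        cxPx <- (sxNm / 2) / pixelSizeNm
        cyPx <- (syNm / 2) / pixelSizeNm
        peak <- exp(-(sxNm^2 + syNm^2) / excWaistNm^2)
        kern <- peak * outer(exp(-(kIdx - cyPx)^2 / (2 * sigmaPx^2)),
                             exp(-(kIdx - cxPx)^2 / (2 * sigmaPx^2)))
        lam <- .conv2(rates, kern) * dwellUs * 1e-6
        lam[lam < 0] <- 0
        counts <- matrix(stats::rpois(length(lam), lam), nY, nX)
        tot <- sum(counts)
        if (tot == 0) next
        pix <- rep(which(counts > 0), counts[counts > 0])  # linear (y,x) idx
        y <- (pix - 1L) %% nY; x <- (pix - 1L) %/% nY
        pixelIndex <- y * nX + x                         # row-major raster
        t <- pixelIndex * dwellNs + stats::runif(tot) * dwellNs
        m <- stats::rexp(tot, rate = 1 / comp$lifetimeNs) +
          laser@irfOffsetNs +
          stats::rnorm(tot, 0, laser@irfSigmaNs)
        m <- m %% laser@repPeriodNs
        chan <- c(chan, rep.int(ch, tot)); tAbs <- c(tAbs, t)
        micro <- c(micro, m)
      }
    }
    o <- order(tAbs)
    scan <- ScanMetadata(mode = "raster", pixelDwellUs = dwellUs,
                         nX = nX, nY = nY, pixelSizeNm = pixelSizeNm)
    PhotonStream(channel = chan[o], tAbsNs = round(tAbs[o]),
                 microtimeNs = round(micro[o] * 1e3) / 1e3,
                 geometry = geometry, laser = laser, scan = scan,
                 durationS = nX * nY * dwellUs * 1e-6)
  })
}
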