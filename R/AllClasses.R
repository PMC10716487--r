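#' @importFrom methods new validObject is setClass setGeneric setMethod
#'   setValidity show slot
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Detector geometry of the SPAD array plus single-element detector
#'
#' Describes the 5x5 asynchronous read-out SPAD array (channels 0-24 in
#' row-major order, central element at index 12) and the auxiliary
#' single-element detector (channel 25), together with the calibrated
#' 1/e^2 lateral waists and axial eccentricities of the named detection
#' volumes. The waists are the values obtained by circular-scanning FCS
#' calibration: 276 nm (central element), 330 nm (sum 3x3), 390 nm
#' (sum 5x5); the axial 1/e^2 half-height is `k * omega0` with `k = 4.5`
#' for the central volume and `k = 4.1` for the summed volumes.
#'
#' @slot nRows,nCols integer array dimensions (default 5x5).
#' @slot pitchSampleNm projected element pitch in the sample plane (nm).
#' @slot waists named numeric, 1/e^2 lateral waist per named volume (nm).
#' @slot eccentricities named numeric, axial elongation k per named volume.
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(nRows = "integer", nCols = "integer",
                 pitchSampleNm = "numeric", waists = "numeric",
                 eccentricities = "numeric"))

setValidity("DetectorGeometry", function(object) {
  req <- c("central", "sum3x3", "sum5x5", "single_element")
  if (!all(req %in% names(object@waists)))
    return(sprintf("waists must be named with %s", paste(req, collapse = ", ")))
  if (!all(req %in% names(object@eccentricities)))
    return("eccentricities must name the same volumes as waists")
  w <- object@waists[c("central", "sum3x3", "sum5x5")]
  if (any(object@waists <= 0)) return("waists must be positive")
  if (is.unsorted(w)) return("waists must be non-decreasing central -> sum5x5")
  if (any(object@eccentricities <= 1)) return("eccentricities k must be > 1")
  if (object@nRows < 1L || object@nCols < 1L) return("invalid array shape")
  TRUE
})

#' @param nRows,nCols array dimensions.
#' @param pitchSampleNm projected element pitch in the sample plane (nm).
#' @param waists named waists (nm) for central, sum3x3, sum5x5,
#'   single_element volumes.
#' @param eccentricities named axial elongations k.
#' @return A `DetectorGeometry` object.
#' @rdname DetectorGeometry-class
#' @export
DetectorGeometry <- function(nRows = 5L, nCols = 5L, pitchSampleNm = 175,
                             waists = c(central = 276, sum3x3 = 330,
                                        sum5x5 = 390, single_element = 330),
                             eccentricities = c(central = 4.5, sum3x3 = 4.1,
                                                sum5x5 = 4.1,
                                                single_element = 4.1)) {
  new("DetectorGeometry", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pitchSampleNm = pitchSampleNm, waists = waists,
      eccentricities = eccentricities)
}

#' Pulsed-laser and TCSPC timing configuration
#'
#' @slot repPeriodNs laser repetition period T_rep (ns); microtimes live in
#'   `[0, repPeriodNs)` after folding.
#' @slot irfSigmaNs Gaussian instrument-response width (ns).
#' @slot irfOffsetNs IRF centre, i.e. the delay of the decay rise (ns).
#' @slot wavelengthNm named excitation wavelengths per color (nm).
#' @exportClass LaserConfig
setClass("LaserConfig",
  representation(repPeriodNs = "numeric", irfSigmaNs = "numeric",
                 irfOffsetNs = "numeric", wavelengthNm = "numeric"))

setValidity("LaserConfig", function(object) {
  if (object@repPeriodNs <= 0) return("repPeriodNs must be > 0")
  if (object@irfSigmaNs < 0) return("irfSigmaNs must be >= 0")
  TRUE
})

#' @param repPeriodNs repetition period (ns); default 25 ns (40 MHz).
#' @param irfSigmaNs,irfOffsetNs Gaussian IRF width and centre (ns).
#' @param wavelengthNm named excitation wavelengths (nm).
#' @return A `LaserConfig` object.
#' @rdname LaserConfig-class
#' @export
LaserConfig <- function(repPeriodNs = 25, irfSigmaNs = 0.1, irfOffsetNs = 2,
                        wavelengthNm = c(green = 485, red = 561)) {
  new("LaserConfig", repPeriodNs = repPeriodNs, irfSigmaNs = irfSigmaNs,
      irfOffsetNs = irfOffsetNs, wavelengthNm = wavelengthNm)
}

#' Scan trajectory metadata
#'
#' @slot mode one of `"point"`, `"circular"`, `"raster"`.
#' @slot pixelDwellUs raster pixel dwell time (us).
#' @slot nX,nY raster frame size in pixels.
#' @slot pixelSizeNm raster pixel size in the sample plane (nm).
#' @slot radiusNm,periodUs circular-scan radius (nm) and period (us).
#' @exportClass ScanMetadata
setClass("ScanMetadata",
  representation(mode = "character", pixelDwellUs = "numeric",
                 nX = "integer", nY = "integer", pixelSizeNm = "numeric",
                 radiusNm = "numeric", periodUs = "numeric"))

setValidity("ScanMetadata", function(object) {
  if (!object@mode %in% c("point", "circular", "raster"))
    return("mode must be point, circular or raster")
  if (object@mode == "raster" && object@nX * object@nY < 1L)
    return("raster requires nX * nY >= 1")
  if (object@mode == "circular" && object@radiusNm <= 0)
    return("circular requires radiusNm > 0")
  TRUE
})

#' @param mode scan mode.
#' @param pixelDwellUs,nX,nY,pixelSizeNm raster parameters.
#' @param radiusNm,periodUs circular-scan parameters.
#' @return A `ScanMetadata` object.
#' @rdname ScanMetadata-class
#' @export
ScanMetadata <- function(mode = c("point", "circular", "raster"),
                         pixelDwellUs = 0, nX = 0L, nY = 0L, pixelSizeNm = 0,
                         radiusNm = 0, periodUs = 0) {
  new("ScanMetadata", mode = match.arg(mode), pixelDwellUs = pixelDwellUs,
      nX = as.integer(nX), nY = as.integer(nY), pixelSizeNm = pixelSizeNm,
      radiusNm = radiusNm, periodUs = periodUs)
}

setClassUnion("ScanMetadataOrNULL", c("ScanMetadata", "NULL"))

#' Photon-resolved event stream
#'
#' The universal currency of the toolkit: one record per detected photon,
#' carrying the detector channel (0-24 array elements, 25 single-element
#' detector), the absolute time in ns since experiment start, and the
#' TCSPC microtime (start-stop time) in ns, `NA` when acquired in
#' intensity mode. Records are time-ordered.
#'
#' @slot channel integer channel per photon.
#' @slot tAbsNs absolute times (ns), non-decreasing.
#' @slot microtimeNs microtimes (ns) or `NA`.
#' @slot geometry a [DetectorGeometry-class].
#' @slot laser a [LaserConfig-class].
#' @slot scan a [ScanMetadata-class] or `NULL`.
#' @slot durationS total acquisition time (s).
#' @slot volume name of the detection volume the stream was merged to
#'   (`""` for a raw multi-channel stream).
#' @exportClass PhotonStream
setClass("PhotonStream",
  representation(channel = "integer", tAbsNs = "numeric",
                 microtimeNs = "numeric", geometry = "DetectorGeometry",
                 laser = "LaserConfig", scan = "ScanMetadataOrNULL",
                 durationS = "numeric", volume = "character"))

setValidity("PhotonStream", function(object) {
  n <- length(object@tAbsNs)
  if (length(object@channel) != n || length(object@microtimeNs) != n)
    return("channel, tAbsNs and microtimeNs must have equal length")
  if (n > 0) {
    maxCh <- object@geometry@nRows * object@geometry@nCols  # + single element
    if (min(object@channel) < 0L || max(object@channel) > maxCh)
      return(sprintf("channel indices must lie in 0..%d", maxCh))
    if (is.unsorted(object@tAbsNs)) return("tAbsNs must be non-decreasing")
    if (object@tAbsNs[1] < 0) return("tAbsNs must be non-negative")
    if (object@durationS * 1e9 < object@tAbsNs[n] - 1e-6)
      return("durationS must cover max(tAbsNs)")
  }
  TRUE
})

#' @param channel,tAbsNs,microtimeNs photon records (parallel vectors).
#' @param geometry,laser,scan acquisition metadata.
#' @param durationS total acquisition time (s); defaults to the last photon.
#' @param volume named volume tag (set by [mergeChannels()]).
#' @return A `PhotonStream` object.
#' @rdname PhotonStream-class
#' @export
PhotonStream <- function(channel = integer(0), tAbsNs = numeric(0),
                         microtimeNs = rep(NA_real_, length(tAbsNs)),
                         geometry = DetectorGeometry(),
                         laser = LaserConfig(), scan = NULL,
                         durationS = if (length(tAbsNs)) max(tAbsNs) / 1e9 else 0,
                         volume = "") {
  new("PhotonStream", channel = as.integer(channel),
      tAbsNs = as.numeric(tAbsNs), microtimeNs = as.numeric(microtimeNs),
      geometry = geometry, laser = laser, scan = scan,
      durationS = durationS, volume = volume)
}

#' Binned intensity trace
#'
#' @slot binWidthUs bin width (us), >= 0.5.
#' @slot counts photon counts per bin.
#' @slot t0Us start time of the first bin (us).
#' @slot volume detection volume the counts were taken from.
#' @exportClass IntensityTrace
setClass("IntensityTrace",
  representation(binWidthUs = "numeric", counts = "numeric",
                 t0Us = "numeric", volume = "character"))

setValidity("IntensityTrace", function(object) {
  if (object@binWidthUs < 0.5) return("binWidthUs must be >= 0.5 us")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Quasi-logarithmic lag grid for correlation curves
#'
#' @slot lagsUs strictly increasing lag times (us).
#' @slot pointsPerDecade grid density.
#' @slot tauMinUs,tauMaxS grid range.
#' @exportClass LagDesign
setClass("LagDesign",
  representation(lagsUs = "numeric", pointsPerDecade = "numeric",
                 tauMinUs = "numeric", tauMaxS = "numeric"))

#' Auto- or cross-correlation curve on photon streams
#'
#' @slot lagsS lag times (s).
#' @slot G correlation values `G(tau)` (dimensionless, zero baseline).
#' @slot replicates per-chunk replicate curves (lags x chunks kept), or NULL.
#' @slot nChunksUsed,nChunksTotal chunk bookkeeping.
#' @slot kind `"auto"` or `"cross"`.
#' @slot volumes names of the correlated detection volumes/colors.
#' @exportClass CorrelationCurve
setClass("CorrelationCurve",
  representation(lagsS = "numeric", G = "numeric",
                 replicates = "matrixOrNULL", nChunksUsed = "integer",
                 nChunksTotal = "integer", kind = "character",
                 volumes = "character"))

setValidity("CorrelationCurve", function(object) {
  if (length(object@G) != length(object@lagsS))
    return("G and lagsS must have equal length")
  if (!object@kind %in% c("auto", "cross")) return("kind must be auto/cross")
  if (!is.null(object@replicates) &&
      nrow(object@replicates) != length(object@lagsS))
    return("replicates must have one row per lag")
  TRUE
})

#' FCS model fit
#'
#' Stores the weighted least-squares fit of a 1- or 2-component 3D-Gaussian
#' FCS model (optionally with the circular-scanning factor) to a
#' [CorrelationCurve-class], including derived diffusion coefficients
#' `D = omega0^2 / (4 tauD)`.
#'
#' @slot estimates,se named fitted parameters and standard errors.
#' @slot fixed named parameters held fixed.
#' @slot model `"3d"` or `"scan"`.
#' @slot nComponents 1 or 2.
#' @slot D,DSe diffusion coefficients per component (um^2/s).
#' @slot chisqRed reduced chi-square.
#' @slot lagsS,G,fitted the fitted data and model curve.
#' @slot volume detection volume name.
#' @exportClass FCSFit
setClass("FCSFit",
  representation(estimates = "numeric", se = "numeric", fixed = "numeric",
                 model = "character", nComponents = "integer", D = "numeric",
                 DSe = "numeric", chisqRed = "numeric", lagsS = "numeric",
                 G = "numeric", fitted = "numeric", volume = "character"))

#' Diffusion-law regression result
#'
#' Linear regression `tauD = omega0^2 / (4 D) + t0` over the nested
#' detection volumes; the sign of the intercept t0 classifies the motion:
#' free (t0 compatible with 0), hop/domain (t0 > 0), meshwork (t0 < 0).
#'
#' @slot omega0SqUm2,tauDMs,tauDSeMs regression points.
#' @slot slope,slopeSe slope (ms/um^2) and its standard error.
#' @slot t0Ms,t0SeMs intercept (ms) and its standard error.
#' @slot DLaw diffusion coefficient from the slope, `1/(4 slope)` (um^2/s).
#' @slot motionClass `"free"`, `"hop_or_domain"` or `"meshwork"`.
#' @slot volumes point labels.
#' @exportClass DiffusionLawResult
setClass("DiffusionLawResult",
  representation(omega0SqUm2 = "numeric", tauDMs = "numeric",
                 tauDSeMs = "numeric", slope = "numeric", slopeSe = "numeric",
                 t0Ms = "numeric", t0SeMs = "numeric", DLaw = "numeric",
                 motionClass = "character", volumes = "character"))

#' Confinement-strength result
#'
#' `S_conf = D(central) / D(sum5x5)`: 1 for free diffusion, < 1 for
#' domain-confined motion, > 1 for meshwork hindrance.
#'
#' @slot sConf,se ratio and first-order propagated error.
#' @slot componentUsed which diffusing component entered the ratio.
#' @exportClass ConfinementResult
setClass("ConfinementResult",
  representation(sConf = "numeric", se = "numeric",
                 componentUsed = "character"))

#' TCSPC decay histogram
#'
#' @slot binEdgesNs uniform bin edges over `[0, repPeriodNs)`.
#' @slot counts photon counts per bin.
#' @slot source channel set or pixel the histogram was built from.
#' @slot repPeriodNs laser period the microtimes are folded by.
#' @exportClass DecayHistogram
setClass("DecayHistogram",
  representation(binEdgesNs = "numeric", counts = "numeric",
                 source = "character", repPeriodNs = "numeric"))

setValidity("DecayHistogram", function(object) {
  if (length(object@counts) != length(object@binEdgesNs) - 1)
    return("counts must have length(binEdgesNs) - 1")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Mono-exponential lifetime fit
#'
#' @slot tauNs,tauSeNs fitted lifetime and standard error (ns).
#' @slot amplitude,background fitted `A` and `B` of `A exp(-t/tau) + B`.
#' @slot windowNs tail-fit window (ns).
#' @exportClass LifetimeFit
setClass("LifetimeFit",
  representation(tauNs = "numeric", tauSeNs = "numeric",
                 amplitude = "numeric", background = "numeric",
                 windowNs = "numeric"))

#' Phasor coordinates of decay histograms
#'
#' First-harmonic cosine/sine Fourier coordinates `(g, s)` of one or many
#' decays (`omega = 2 pi n / T_rep`). Calibrated mono-exponential decays lie
#' on the universal semicircle `g^2 + s^2 = g`.
#'
#' @slot g,s phasor coordinates.
#' @slot counts photons backing each point.
#' @slot harmonic harmonic number n.
#' @slot omega angular frequency (rad/ns).
#' @slot calibrated whether a [PhasorCalibration-class] has been applied.
#' @slot imageDim image dimensions when the points are pixels, else
#'   `integer(0)`.
#' @slot pixelIndex linear pixel indices (thresholded pixels) when the
#'   points are pixels.
#' @exportClass PhasorSet
setClass("PhasorSet",
  representation(g = "numeric", s = "numeric", counts = "numeric",
                 harmonic = "integer", omega = "numeric",
                 calibrated = "logical", imageDim = "integer",
                 pixelIndex = "integer"))

#' Phasor calibration transform
#'
#' Rotation + modulation scaling that maps the measured phasor of a
#' reference dye of known lifetime onto its theoretical position on the
#' universal circle.
#'
#' @slot rotation rotation angle (rad).
#' @slot scale modulation scale factor.
#' @slot tauRefNs reference lifetime (ns).
#' @exportClass PhasorCalibration
setClass("PhasorCalibration",
  representation(rotation = "numeric", scale = "numeric",
                 tauRefNs = "numeric"))

#' 4D photon-counting histogram (channel, x, y, microtime)
#'
#' @slot counts 4D array with dimensions (y, x, channel, dtBin).
#' @slot pixelSizeNm pixel size (nm).
#' @slot microtimeEdgesNs microtime bin edges (ns).
#' @slot geometry,laser acquisition metadata.
#' @exportClass ISMStack
setClass("ISMStack",
  representation(counts = "array", pixelSizeNm = "numeric",
                 microtimeEdgesNs = "numeric", geometry = "DetectorGeometry",
                 laser = "LaserConfig"))

#' Shift-vector fingerprint for adaptive pixel reassignment
#'
#' @slot shifts channel x 2 matrix of lateral shifts (dy, dx, pixels)
#'   relative to the central element.
#' @slot confidence phase-correlation peak height per channel.
#' @slot lowConfidence channels whose shift fell back to the fitted
#'   geometric model.
#' @exportClass ShiftFingerprint
setClass("ShiftFingerprint",
  representation(shifts = "matrix", confidence = "numeric",
                 lowConfidence = "logical"))

setValidity("ShiftFingerprint", function(object) {
  if (ncol(object@shifts) != 2) return("shifts must be a channel x 2 matrix")
  TRUE
})

#' Reassigned ISM image
#'
#' @slot intensity reassigned, channel-summed 2D intensity image.
#' @slot timeResolved optional (y, x, dtBin) time-resolved stack.
#' @slot lifetimeMapNs optional per-pixel lifetime map (ns).
#' @slot pixelSizeNm pixel size (nm).
#' @slot cropPx border pixels cropped by the maximum reassignment shift.
#' @slot fingerprint the [ShiftFingerprint-class] used.
#' @exportClass ISMImage
setClass("ISMImage",
  representation(intensity = "matrix", timeResolved = "arrayOrNULL",
                 lifetimeMapNs = "matrixOrNULL", pixelSizeNm = "numeric",
                 cropPx = "integer", fingerprint = "ShiftFingerprint"))

#' k-means clustering result with elbow selection
#'
#' @slot k selected number of clusters.
#' @slot assignments cluster label per point (labels canonicalized by
#'   centroid order).
#' @slot centroids k x d centroid matrix (original feature scale).
#' @slot inertia within-cluster sum of squares per candidate k.
#' @slot ellipses per-cluster covariance confidence ellipses.
#' @slot standardized whether features were z-scored before clustering.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(k = "integer", assignments = "integer",
                 centroids = "matrix", inertia = "numeric",
                 ellipses = "list", standardized = "logical"))
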