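#' TCSPC decay histogram
#'
#' Histograms folded microtimes into `nBins` uniform bins over
#' `[0, T_rep)`. Counts are conserved: every photon of the selection falls
#' in exactly one bin.
#'
#' @param stream a [PhotonStream-class] with (folded) microtimes.
#' @param nBins number of TCSPC bins (default 256).
#' @param volume optional named volume to merge to first.
#' @return A [DecayHistogram-class].
#' @export
decayHistogram <- function(stream, nBins = 256, volume = NULL) {
  if (!is.null(volume)) stream <- mergeChannels(stream, volume)
  m <- stream@microtimeNs
  m <- m[!is.na(m)]
  if (!length(m))
    stop("stream carries no microtimes (intensity-mode acquisition)")
  Trep <- stream@laser@repPeriodNs
  if (any(m < 0 | m >= Trep))
    stop("microtimes outside [0, T_rep); call foldMicrotime() first")
  edges <- seq(0, Trep, length.out = nBins + 1)
  idx <- pmin(nBins, floor(m / Trep * nBins) + 1L)
  counts <- as.numeric(tabulate(idx, nbins = nBins))
  src <- if (!is.null(volume)) volume
         else if (nzchar(stream@volume)) stream@volume else "all"
  new("DecayHistogram", binEdgesNs = edges, counts = counts, source = src,
      repPeriodNs = Trep)
}

.binCenters <- function(hist) {
  e <- hist@binEdgesNs
  (e[-1] + e[-length(e)]) / 2
}

#' Tail fit of a mono-exponential decay
#'
#' Least-squares fit of `A exp(-t / tau) + B` to the decay histogram on a
#' tail window. By default the window starts 0.5 ns after the histogram
#' peak, excluding the IRF-dominated rise (no IRF reconvolution is
#' attempted), and extends to the end of the period.
#'
#' @param hist a [DecayHistogram-class].
#' @param windowNs numeric length-2 fit window (ns); `NULL` for the
#'   default tail window.
#' @param tailOffsetNs gap between the histogram peak and the default
#'   window start (ns).
#' @return A [LifetimeFit-class].
#' @export
fitMonoexp <- function(hist, windowNs = NULL, tailOffsetNs = 0.5) {
  tc <- .binCenters(hist)
  if (is.null(windowNs)) {
    peak <- tc[which.max(hist@counts)]
    windowNs <- c(peak + tailOffsetNs, max(hist@binEdgesNs))
  }
  sel <- tc >= windowNs[1] & tc <= windowNs[2]
  if (sum(sel) < 5)
    stop("tail window holds fewer than 5 bins")
  t <- tc[sel]; y <- hist@counts[sel]
  t0 <- t[1]
  # log-linear start values on positive counts
  pos <- y > 0
  tau0 <- if (sum(pos) > 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else hist@repPeriodNs / 5
  } else hist@repPeriodNs / 5
  start <- list(A = max(y), tau = unname(tau0), B = max(min(y), 0))
  residFun <- function(p)
    p[["A"]] * exp(-(t - t0) / p[["tau"]]) + p[["B"]] - y
  fit <- .lmFit(residFun, start,
                lower = c(0, 1e-3, 0), upper = c(Inf, Inf, Inf))
  est <- unlist(fit$par); se <- .lmSe(fit)
  new("LifetimeFit", tauNs = est[["tau"]], tauSeNs = se[["tau"]],
      amplitude = est[["A"]], background = est[["B"]], windowNs = windowNs)
}

#' Phasor coordinates of decay data
#'
#' Computes the first-harmonic (or `harmonic = n`) phasor coordinates
#' `g = sum c_i cos(w t_i) / sum c_i`, `s = sum c_i sin(w t_i) / sum c_i`
#' with `w = 2 pi n / T_rep`. An ideal mono-exponential lies on the
#' universal semicircle at `(1/(1+(w tau)^2), w tau/(1+(w tau)^2))`.
#'
#' Methods exist for a [DecayHistogram-class] (bin-centre summation), a
#' [PhotonStream-class] (direct photon summation) and an
#' [ISMStack-class] (one point per pixel passing the intensity threshold,
#' default 10% of the maximum pixel count).
#'
#' @param object decay data.
#' @param harmonic harmonic number n.
#' @param ... method-specific arguments (`threshold` for image stacks).
#' @return A [PhasorSet-class].
#' @export
setGeneric("phasor", function(object, harmonic = 1L, ...)
  standardGeneric("phasor"))

#' @rdname phasor
setMethod("phasor", "DecayHistogram", function(object, harmonic = 1L, ...) {
  tot <- sum(object@counts)
  if (tot <= 0) stop("zero counts: cannot compute a phasor")
  w <- 2 * pi * harmonic / object@repPeriodNs
  tc <- .binCenters(object)
  new("PhasorSet", g = sum(object@counts * cos(w * tc)) / tot,
      s = sum(object@counts * sin(w * tc)) / tot, counts = tot,
      harmonic = as.integer(harmonic), omega = w, calibrated = FALSE,
      imageDim = integer(0), pixelIndex = integer(0))
})

#' @rdname phasor
setMethod("phasor", "PhotonStream", function(object, harmonic = 1L, ...) {
  m <- object@microtimeNs
  m <- m[!is.na(m)]
  if (!length(m)) stop("zero counts: cannot compute a phasor")
  Trep <- object@laser@repPeriodNs
  w <- 2 * pi * harmonic / Trep
  new("PhasorSet", g = mean(cos(w * (m %% Trep))),
      s = mean(sin(w * (m %% Trep))), counts = length(m),
      harmonic = as.integer(harmonic), omega = w, calibrated = FALSE,
      imageDim = integer(0), pixelIndex = integer(0))
})

#' @rdname phasor
#' @param threshold keep pixels whose total count exceeds
#'   `threshold * max(pixel counts)`.
setMethod("phasor", "ISMStack", function(object, harmonic = 1L,
                                         threshold = 0.10, ...) {
  .phasorFromCube(.stackTimeCube(object), object@microtimeEdgesNs,
                  object@laser@repPeriodNs, harmonic, threshold)
})

# (y, x, dt) cube -> per-pixel phasors above the intensity threshold
.phasorFromCube <- function(cube, edgesNs, repPeriodNs, harmonic, threshold) {
  d <- dim(cube)
  totals <- apply(cube, c(1, 2), sum)
  keep <- which(totals > threshold * max(totals) & totals > 0)
  if (!length(keep))
    stop("no pixels pass the intensity threshold")
  w <- 2 * pi * harmonic / repPeriodNs
  tc <- (edgesNs[-1] + edgesNs[-length(edgesNs)]) / 2
  flat <- matrix(cube, nrow = d[1] * d[2])
  gs <- flat[keep, , drop = FALSE] %*% cbind(cos(w * tc), sin(w * tc))
  tot <- totals[keep]
  new("PhasorSet", g = gs[, 1] / tot, s = gs[, 2] / tot, counts = tot,
      harmonic = as.integer(harmonic), omega = w, calibrated = FALSE,
      imageDim = d[1:2], pixelIndex = as.integer(keep))
}

#' Phasor calibration against a reference dye
#'
#' Derives the rotation + modulation scaling that maps the measured phasor
#' of a reference of known lifetime (e.g. Atto 495, tau = 1 ns) onto its
#' theoretical position on the universal circle, correcting the fixed
#' instrumental phase delay and modulation loss.
#'
#' @param measuredRef a single-point [PhasorSet-class] of the reference
#'   (needs > 1e4 photons).
#' @param tauRefNs reference lifetime (ns).
#' @return A [PhasorCalibration-class].
#' @export
calibratePhasor <- function(measuredRef, tauRefNs) {
  stopifnot(is(measuredRef, "PhasorSet"), length(measuredRef@g) == 1)
  if (sum(measuredRef@counts) <= 1e4)
    warning("reference phasor backed by <= 1e4 photons; calibration noisy")
  mod <- sqrt(measuredRef@g^2 + measuredRef@s^2)
  if (mod < 1e-9) stop("degenerate (zero-modulus) reference phasor")
  wt <- measuredRef@omega * tauRefNs
  gT <- 1 / (1 + wt^2); sT <- wt / (1 + wt^2)
  new("PhasorCalibration",
      rotation = atan2(sT, gT) - atan2(measuredRef@s, measuredRef@g),
      scale = sqrt(gT^2 + sT^2) / mod, tauRefNs = tauRefNs)
}

#' Apply a phasor calibration
#'
#' Rotates and scales all points of a [PhasorSet-class]. Guarded by a
#' provenance flag: applying a calibration twice is refused.
#'
#' @param phasors a [PhasorSet-class].
#' @param calibration a [PhasorCalibration-class].
#' @return The calibrated [PhasorSet-class].
#' @export
applyPhasorCalibration <- function(phasors, calibration) {
  if (phasors@calibrated)
    stop("phasor set is already calibrated (non-idempotent operation)")
  th <- calibration@rotation; sc <- calibration@scale
  g <- sc * (phasors@g * cos(th) - phasors@s * sin(th))
  s <- sc * (phasors@g * sin(th) + phasors@s * cos(th))
  phasors@g <- g; phasors@s <- s; phasors@calibrated <- TRUE
  phasors
}

#' Lifetime from a single-point phasor
#'
#' `tau = s / (omega g)`, exact for a calibrated mono-exponential decay.
#'
#' @param phasors a [PhasorSet-class].
#' @return Lifetimes (ns) per point.
#' @export
phasorLifetime <- function(phasors) {
  phasors@s / (phasors@omega * phasors@g)
}

#' Centroid-based phasor segmentation
#'
#' Splits the per-pixel phasor cloud at the line through its centroid
#' perpendicular to the g axis and back-projects the two halves into pixel
#' masks: points left of the centroid (smaller g) carry longer lifetimes,
#' points right of it shorter lifetimes. A custom projection axis may be
#' supplied.
#'
#' @param phasors an image [PhasorSet-class] (from an [ISMStack-class] or
#'   time-resolved image).
#' @param axis projection direction in the (g, s) plane; default `c(1, 0)`
#'   (split on g).
#' @return List with `mask` (integer matrix: 0 below threshold, 1 long
#'   lifetime, 2 short lifetime), `degenerate` flag and the `centroid`.
#' @export
phasorSegment <- function(phasors, axis = c(1, 0)) {
  if (!length(phasors@imageDim))
    stop("phasorSegment needs per-pixel phasors (image input)")
  if (!length(phasors@g)) stop("empty phasor cloud after thresholding")
  proj <- phasors@g * axis[1] + phasors@s * axis[2]
  centroid <- c(g = sum(phasors@g * phasors@counts) / sum(phasors@counts),
                s = sum(phasors@s * phasors@counts) / sum(phasors@counts))
  c0 <- centroid[1] * axis[1] + centroid[2] * axis[2]
  mask <- matrix(0L, phasors@imageDim[1], phasors@imageDim[2])
  degenerate <- stats::sd(proj) < 1e-9
  if (degenerate) {
    mask[phasors@pixelIndex] <- 1L
  } else {
    mask[phasors@pixelIndex] <- ifelse(proj < c0, 1L, 2L)
  }
  list(mask = mask, degenerate = degenerate, centroid = centroid)
}
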