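#' Quasi-logarithmic lag grid
#'
#' Defines the lag grid on which correlation curves are evaluated. Lags are
#' spaced `pointsPerDecade` per decade between `tauMinUs` and `tauMaxS`;
#' during correlation each lag is snapped onto an integer multiple of a
#' lag-proportional bin width (multi-tau coarsening), so the effective grid
#' is slightly irregular but strictly increasing.
#'
#' @param pointsPerDecade grid density (default 8).
#' @param tauMinUs smallest lag and base bin width (us).
#' @param tauMaxS largest lag (s).
#' @return A [LagDesign-class].
#' @export
lagDesign <- function(pointsPerDecade = 8, tauMinUs = 1, tauMaxS = 1) {
  stopifnot(tauMinUs > 0, tauMaxS * 1e6 > tauMinUs)
  lags <- 10^seq(log10(tauMinUs), log10(tauMaxS * 1e6),
                 by = 1 / pointsPerDecade)
  new("LagDesign", lagsUs = lags, pointsPerDecade = pointsPerDecade,
      tauMinUs = tauMinUs, tauMaxS = tauMaxS)
}

# Snap the quasi-log grid onto multi-tau (level, k) pairs.
# Level L uses bin width w0 * 2^L; a lag enters level L once it exceeds
# `coarsenAfter` bins, so the bin width stays <= lag / coarsenAfter.
.lagSchedule <- function(design, w0Ns, coarsenAfter = 8) {
  lagNs <- design@lagsUs * 1e3
  lev <- pmax(0, floor(log2(lagNs / (coarsenAfter * w0Ns))))
  k <- pmax(1, round(lagNs / (w0Ns * 2^lev)))
  snapped <- k * w0Ns * 2^lev
  keep <- !duplicated(snapped)
  list(level = as.integer(lev[keep]), k = as.integer(k[keep]),
       lagNs = snapped[keep])
}

.corrWindow <- function(aNs, bNs, t0Ns, t1Ns, design) {
  w0Ns <- design@tauMinUs * 1e3
  n0 <- floor((t1Ns - t0Ns) / w0Ns)
  if (n0 < 4) stop("correlation window shorter than 4 base bins")
  sched <- .lagSchedule(design, w0Ns)
  usable <- sched$lagNs < (n0 * w0Ns) / 2  # need headroom for the products
  res <- cpp_correlate(aNs, bNs, t0Ns, w0Ns, n0,
                       sched$level[usable], sched$k[usable])
  list(lagNs = sched$lagNs[usable], G = res$G)
}

#' Correlate photon streams directly on their time lists
#'
#' Computes the normalized intensity correlation
#' `G(tau) = <dI_a(t) dI_b(t+tau)> / (<I_a><I_b>)` from photon absolute
#' times, by binning at the base lag resolution and coarsening the bin
#' width in proportion to the lag (multi-tau scheme). Normalization is
#' symmetric (local means per lag) to suppress slow-drift bias. On equal
#' bin widths the result is identical to a brute-force binned-trace
#' correlation.
#'
#' @param a,b [PhotonStream-class] objects sharing a time origin; `b`
#'   defaults to `a` (autocorrelation).
#' @param design a [lagDesign()].
#' @param tStartS,tEndS correlation window (s); defaults to the full
#'   acquisition.
#' @param kind `"auto"` or `"cross"` label for the result.
#' @return A [CorrelationCurve-class].
#' @export
correlatePhotons <- function(a, b = a, design = lagDesign(), tStartS = 0,
                             tEndS = min(a@durationS, b@durationS),
                             kind = if (identical(a, b)) "auto" else "cross") {
  if (nPhotons(a) == 0 || nPhotons(b) == 0)
    stop("cannot correlate an empty photon stream")
  res <- .corrWindow(a@tAbsNs, b@tAbsNs, tStartS * 1e9, tEndS * 1e9, design)
  if (all(is.na(res$G)))
    stop("zero mean intensity in the correlation window")
  new("CorrelationCurve", lagsS = res$lagNs * 1e-9, G = res$G,
      replicates = NULL, nChunksUsed = 1L, nChunksTotal = 1L, kind = kind,
      volumes = unique(c(
        if (nzchar(a@volume)) a@volume else "all",
        if (nzchar(b@volume)) b@volume else "all")))
}

# Shared chunked engine for auto- and cross-correlation.
.chunkedCorr <- function(a, b, chunkS, design, kind, volumes,
                         qcIntensityDev = 0.25, qcGNSigma = 5) {
  durS <- min(a@durationS, b@durationS)
  nChunks <- floor(durS / chunkS)
  if (nChunks < 2)
    stop(sprintf("duration %.3g s holds fewer than 2 chunks of %g s",
                 durS, chunkS))
  curves <- vector("list", nChunks)
  meanI <- numeric(nChunks)
  for (i in seq_len(nChunks)) {
    t0 <- (i - 1) * chunkS * 1e9; t1 <- i * chunkS * 1e9
    na <- as.numeric(sum(a@tAbsNs >= t0 & a@tAbsNs < t1))
    nb <- as.numeric(sum(b@tAbsNs >= t0 & b@tAbsNs < t1))
    meanI[i] <- sqrt(na * nb) / chunkS
    curves[[i]] <- .corrWindow(a@tAbsNs, b@tAbsNs, t0, t1, design)
  }
  lagNs <- curves[[1]]$lagNs
  Gmat <- vapply(curves, function(cv) cv$G, numeric(length(lagNs)))
  Gmat <- matrix(Gmat, nrow = length(lagNs))

  # automated curve QC (deterministic stand-in for visual inspection):
  # (1) chunk intensity deviating > qcIntensityDev from the median chunk
  # (2) G at the three smallest lags > qcGNSigma robust SDs off the
  #     replicate median; the robust SD is pooled over the low lags, since
  #     a per-lag MAD over a handful of replicates is too unstable
  # (3) chunks without a usable curve (no photons) are always rejected
  medI <- stats::median(meanI)
  badI <- abs(meanI - medI) > qcIntensityDev * medI
  nLow <- min(3L, length(lagNs))
  low <- Gmat[seq_len(nLow), , drop = FALSE]
  dev <- low - apply(low, 1, stats::median, na.rm = TRUE)
  sdr <- stats::mad(dev, na.rm = TRUE, center = 0)
  badG <- if (is.finite(sdr) && sdr > 0)
    apply(abs(dev) > qcGNSigma * sdr, 2, any) else rep(FALSE, nChunks)
  badG[is.na(badG)] <- TRUE
  noCurve <- apply(Gmat, 2, function(g) !any(is.finite(g))) | meanI == 0
  bad <- badI | badG | noCurve
  if (all(bad)) {
    report <- paste(sprintf("chunk %d: intensity %.3g kHz%s%s",
                            seq_len(nChunks), meanI / 1e3,
                            ifelse(badI, " [intensity outlier]", ""),
                            ifelse(badG, " [G outlier]", "")),
                    collapse = "; ")
    stop("all chunks rejected by QC: ", report)
  }
  keep <- which(!bad)
  G <- rowMeans(Gmat[, keep, drop = FALSE], na.rm = TRUE)
  new("CorrelationCurve", lagsS = lagNs * 1e-9, G = G,
      replicates = Gmat[, keep, drop = FALSE],
      nChunksUsed = length(keep), nChunksTotal = as.integer(nChunks),
      kind = kind, volumes = volumes)
}

#' Chunked autocorrelation with automated curve QC
#'
#' Splits the stream into chunks of 5 or 10 s, correlates each chunk
#' independently, rejects artifact chunks (intensity steps, distorted
#' low-lag amplitudes) by a deterministic quality control, and averages the
#' surviving replicate curves pointwise. Replicates are retained for error
#' estimation.
#'
#' @param stream a [PhotonStream-class] (merge to a volume first, or pass
#'   `volume`).
#' @param chunkS chunk length (s), typically 5 or 10.
#' @param design a [lagDesign()].
#' @param volume optional volume to merge to before correlating.
#' @param qcIntensityDev maximal relative deviation of a chunk's mean
#'   intensity from the median chunk.
#' @param qcGNSigma robust-SD multiple for the low-lag G outlier test.
#' @return A [CorrelationCurve-class] with replicates.
#' @export
chunkedCorrelation <- function(stream, chunkS = 10, design = lagDesign(),
                               volume = NULL, qcIntensityDev = 0.25,
                               qcGNSigma = 5) {
  if (!is.null(volume)) stream <- mergeChannels(stream, volume)
  if (nPhotons(stream) == 0) stop("cannot correlate an empty photon stream")
  .chunkedCorr(stream, stream, chunkS, design, "auto",
               if (nzchar(stream@volume)) stream@volume else "all",
               qcIntensityDev, qcGNSigma)
}

#' Dual-color cross-correlation
#'
#' Correlates the green signal (SPAD array, merged to `greenVolume`,
#' default sum 3x3) against the red signal (single-element detector) of a
#' simultaneous acquisition. The relative amplitude of the resulting
#' cross-correlation curve reports the co-diffusing (interacting) fraction.
#'
#' @param green,red [PhotonStream-class] objects sharing a time origin
#'   (may be the same object for a split-signal control).
#' @param design a [lagDesign()].
#' @param chunkS optional chunk length (s) for QC-averaged curves; `NULL`
#'   correlates the whole stream at once.
#' @param greenVolume array volume for the green channel set.
#' @return A [CorrelationCurve-class] with `kind = "cross"`.
#' @export
crossColorCorrelation <- function(green, red, design = lagDesign(),
                                  chunkS = NULL, greenVolume = "sum3x3") {
  g <- if (nzchar(green@volume)) green else mergeChannels(green, greenVolume)
  r <- if (nzchar(red@volume)) red else mergeChannels(red, "single_element")
  if (nPhotons(g) == 0 || nPhotons(r) == 0)
    stop("cannot correlate an empty photon stream")
  vols <- c(g@volume, r@volume)
  if (is.null(chunkS)) {
    cv <- correlatePhotons(g, r, design, kind = "cross")
    cv@volumes <- vols
    cv
  } else {
    .chunkedCorr(g, r, chunkS, design, "cross", vols)
  }
}
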