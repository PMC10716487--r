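#' Channel indices of a named detection volume
#'
#' Maps the named virtual detection volumes onto SPAD channel sets: the
#' central element, the inner 3x3 block, the full array, or the
#' single-element detector (the channel after the last array element).
#'
#' @param geometry a [DetectorGeometry-class].
#' @param volume one of `"central"`, `"sum3x3"`, `"sum5x5"`,
#'   `"single_element"`.
#' @return Integer channel indices (0-based).
#' @export
volumeChannels <- function(geometry, volume) {
  nr <- geometry@nRows; nc <- geometry@nCols
  cr <- nr %/% 2L; cc <- nc %/% 2L
  idx <- function(r, c) r * nc + c
  switch(volume,
    central = idx(cr, cc),
    sum3x3 = {
      rs <- pmax(0L, cr - 1L):pmin(nr - 1L, cr + 1L)
      cs <- pmax(0L, cc - 1L):pmin(nc - 1L, cc + 1L)
      as.integer(outer(rs, cs, idx))
    },
    sum5x5 = 0:(nr * nc - 1L),
    single_element = nr * nc,
    stop(sprintf("unknown volume name '%s'", volume))
  )
}

#' Merge SPAD channels into a virtual detection volume
#'
#' Selects the photons of the channels forming the named volume (e.g. the
#' inner 3x3 block) and returns them as one time-ordered stream tagged with
#' that volume, whose calibrated waist is carried by the stream's geometry.
#' Photon counts are conserved: the output holds exactly the photons whose
#' channel is in the named set.
#'
#' @param stream a [PhotonStream-class].
#' @param volume name of the virtual volume.
#' @return A [PhotonStream-class] restricted to the selected channels.
#' @examples
#' s <- simulatePhotonStream(durationS = 0.2, seed = 1)
#' mergeChannels(s, "sum3x3")
#' @export
mergeChannels <- function(stream, volume = c("central", "sum3x3", "sum5x5",
                                             "single_element")) {
  volume <- match.arg(volume)
  chans <- volumeChannels(stream@geometry, volume)
  keep <- stream@channel %in% chans
  new("PhotonStream", channel = stream@channel[keep],
      tAbsNs = stream@tAbsNs[keep], microtimeNs = stream@microtimeNs[keep],
      geometry = stream@geometry, laser = stream@laser, scan = stream@scan,
      durationS = stream@durationS, volume = volume)
}

#' Bin a photon stream into an intensity trace
#'
#' Counts photons into uniform bins of the absolute time axis:
#' `counts[i]` is the number of photons with `t_abs` in `[i w, (i+1) w)`.
#' The total count equals the number of photons in the selection.
#'
#' @param stream a [PhotonStream-class].
#' @param binWidthUs bin width (us), at least 0.5 (the detector's shortest
#'   sampling bin).
#' @param volume optional volume to merge to first (`NULL`: use the stream
#'   as is).
#' @return An [IntensityTrace-class].
#' @export
binIntensity <- function(stream, binWidthUs, volume = NULL) {
  if (!is.numeric(binWidthUs) || binWidthUs <= 0)
    stop("binWidthUs must be positive")
  if (binWidthUs < 0.5)
    stop("binWidthUs must be >= 0.5 us")
  if (!is.null(volume)) stream <- mergeChannels(stream, volume)
  wNs <- binWidthUs * 1e3
  nBins <- max(1L, as.integer(ceiling(stream@durationS * 1e9 / wNs - 1e-9)))
  counts <- numeric(nBins)
  if (nPhotons(stream) > 0) {
    i <- pmin(nBins, floor(stream@tAbsNs / wNs) + 1)
    tab <- tabulate(i, nbins = nBins)
    counts <- as.numeric(tab)
  }
  new("IntensityTrace", binWidthUs = binWidthUs, counts = counts, t0Us = 0,
      volume = if (is.null(volume)) stream@volume else volume)
}

#' Fold microtimes by the laser repetition period
#'
#' Replaces every microtime by its value modulo the repetition period
#' (the MOD operation on the TCSPC axis), so that all folded values lie in
#' `[0, T_rep)`. Idempotent.
#'
#' @param stream a [PhotonStream-class] with microtimes.
#' @return The stream with folded microtimes.
#' @export
foldMicrotime <- function(stream) {
  if (nPhotons(stream) > 0 && all(is.na(stream@microtimeNs)))
    stop("stream carries no microtimes (intensity-mode acquisition)")
  Trep <- stream@laser@repPeriodNs
  m <- stream@microtimeNs %% Trep
  m[m < 0] <- m[m < 0] + Trep
  stream@microtimeNs <- m
  stream
}
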