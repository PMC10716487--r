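#' @name photonFFS-accessors
#' @title Accessors for photonFFS data classes
#' @description Slot accessors for the photon-stream, correlation and fit
#'   containers. Accessors are preferred over direct slot access.
#' @param object a photonFFS object.
#' @return The corresponding slot value.
NULL

#' @rdname photonFFS-accessors
#' @export
setGeneric("nPhotons", function(object) standardGeneric("nPhotons"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("absTimes", function(object) standardGeneric("absTimes"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("microtimes", function(object) standardGeneric("microtimes"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("laserConfig", function(object) standardGeneric("laserConfig"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("scanMeta", function(object) standardGeneric("scanMeta"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("acqDuration", function(object) standardGeneric("acqDuration"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("volumeName", function(object) standardGeneric("volumeName"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("lags", function(object) standardGeneric("lags"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("corrValues", function(object) standardGeneric("corrValues"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("replicateCurves", function(object) standardGeneric("replicateCurves"))
#' @rdname photonFFS-accessors
#' @export
setGeneric("diffusionCoefficient",
           function(object) standardGeneric("diffusionCoefficient"))

#' @rdname photonFFS-accessors
setMethod("nPhotons", "PhotonStream", function(object) length(object@tAbsNs))
#' @rdname photonFFS-accessors
setMethod("channels", "PhotonStream", function(object) object@channel)
#' @rdname photonFFS-accessors
setMethod("absTimes", "PhotonStream", function(object) object@tAbsNs)
#' @rdname photonFFS-accessors
setMethod("microtimes", "PhotonStream", function(object) object@microtimeNs)
#' @rdname photonFFS-accessors
setMethod("geometry", "PhotonStream", function(object) object@geometry)
#' @rdname photonFFS-accessors
setMethod("laserConfig", "PhotonStream", function(object) object@laser)
#' @rdname photonFFS-accessors
setMethod("scanMeta", "PhotonStream", function(object) object@scan)
#' @rdname photonFFS-accessors
setMethod("acqDuration", "PhotonStream", function(object) object@durationS)
#' @rdname photonFFS-accessors
setMethod("volumeName", "PhotonStream", function(object) object@volume)

#' @rdname photonFFS-accessors
setMethod("lags", "CorrelationCurve", function(object) object@lagsS)
#' @rdname photonFFS-accessors
setMethod("corrValues", "CorrelationCurve", function(object) object@G)
#' @rdname photonFFS-accessors
setMethod("replicateCurves", "CorrelationCurve",
          function(object) object@replicates)
#' @rdname photonFFS-accessors
setMethod("volumeName", "CorrelationCurve", function(object) object@volumes)

#' @rdname photonFFS-accessors
setMethod("diffusionCoefficient", "FCSFit", function(object) object@D)
#' @rdname photonFFS-accessors
#' @importFrom stats coef
setMethod("coef", "FCSFit", function(object) object@estimates)
#' @rdname photonFFS-accessors
setMethod("volumeName", "FCSFit", function(object) object@volume)

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %dx%d SPAD array + single element\n",
              object@nRows, object@nCols))
  cat(sprintf("  pitch (sample plane): %.0f nm\n", object@pitchSampleNm))
  w <- object@waists; k <- object@eccentricities
  for (nm in names(w))
    cat(sprintf("  %-14s omega0 = %3.0f nm, k = %.1f\n", nm, w[nm], k[nm]))
})

setMethod("show", "PhotonStream", function(object) {
  cat(sprintf("PhotonStream: %d photons over %.3f s\n",
              nPhotons(object), object@durationS))
  if (nzchar(object@volume))
    cat(sprintf("  merged volume: %s\n", object@volume))
  if (nPhotons(object) > 0) {
    cat(sprintf("  channels: %s\n",
                paste(sort(unique(object@channel)), collapse = " ")))
    cat(sprintf("  microtimes: %s\n",
                if (all(is.na(object@microtimeNs))) "absent (intensity mode)"
                else "present"))
  }
  if (!is.null(object@scan)) cat(sprintf("  scan: %s\n", object@scan@mode))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve (%s): %d lags, %.2g..%.2g s\n", object@kind,
              length(object@lagsS), min(object@lagsS), max(object@lagsS)))
  cat(sprintf("  volumes: %s\n", paste(object@volumes, collapse = " x ")))
  if (object@nChunksTotal > 0)
    cat(sprintf("  chunks: %d used of %d\n", object@nChunksUsed,
                object@nChunksTotal))
})

setMethod("show", "FCSFit", function(object) {
  cat(sprintf("FCSFit (%s, %d component%s) on volume '%s'\n", object@model,
              object@nComponents, if (object@nComponents > 1) "s" else "",
              object@volume))
  est <- object@estimates
  for (nm in names(est))
    cat(sprintf("  %-10s %10.4g +/- %.2g\n", nm, est[nm],
                object@se[nm]))
  cat(sprintf("  D = %s um^2/s; reduced chi^2 = %.3g\n",
              paste(sprintf("%.3g", object@D), collapse = ", "),
              object@chisqRed))
})

setMethod("show", "DiffusionLawResult", function(object) {
  cat("Diffusion law tauD = omega0^2/(4D) + t0\n")
  cat(sprintf("  t0 = %.4g +/- %.2g ms; D_law = %.3g um^2/s\n",
              object@t0Ms, object@t0SeMs, object@DLaw))
  cat(sprintf("  motion class: %s\n", object@motionClass))
})

setMethod("show", "ConfinementResult", function(object) {
  cat(sprintf("Confinement strength S_conf = %.3g +/- %.2g (%s component)\n",
              object@sConf, object@se, object@componentUsed))
})

setMethod("show", "LifetimeFit", function(object) {
  cat(sprintf("LifetimeFit: tau = %.3f +/- %.3f ns (tail %.2f..%.1f ns)\n",
              object@tauNs, object@tauSeNs, object@windowNs[1],
              object@windowNs[2]))
})

setMethod("show", "PhasorSet", function(object) {
  cat(sprintf("PhasorSet: %d point%s, harmonic %d, %scalibrated\n",
              length(object@g), if (length(object@g) != 1) "s" else "",
              object@harmonic, if (object@calibrated) "" else "not "))
  if (length(object@g) == 1)
    cat(sprintf("  (g, s) = (%.4f, %.4f)\n", object@g, object@s))
})

setMethod("show", "ISMStack", function(object) {
  d <- dim(object@counts)
  cat(sprintf("ISMStack: %d x %d pixels, %d channels, %d microtime bins\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  %.0f nm pixels, %d photons\n", object@pixelSizeNm,
              sum(object@counts)))
})

setMethod("show", "ISMImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ISMImage: %d x %d pixels (%.0f nm), border crop %d px\n",
              d[1], d[2], object@pixelSizeNm, object@cropPx))
  cat(sprintf("  lifetime map: %s; time-resolved stack: %s\n",
              if (is.null(object@lifetimeMapNs)) "no" else "yes",
              if (is.null(object@timeResolved)) "no" else "yes"))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d (%d points)\n", object@k,
              length(object@assignments)))
})
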