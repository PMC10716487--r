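#' Columnar on-disk event-list format
#'
#' Photon streams are persisted as a self-describing text container: a
#' versioned magic line, one JSON metadata line (detector geometry, laser
#' configuration, scan metadata, duration, volume tag), then one
#' tab-separated row per photon with columns `channel` (uint8),
#' `t_abs_ns` (integer nanoseconds) and `microtime_ps` (integer picosecond
#' ticks, empty in intensity mode). Integer time columns avoid float drift
#' on long acquisitions; microtimes are quantized to 1 ps on write.
#'
#' @param stream a [PhotonStream-class].
#' @param path file path.
#' @return `writeEventList` invisibly returns `path`; `readEventList`
#'   returns the reconstructed [PhotonStream-class].
#' @examples
#' f <- tempfile(fileext = ".pffs")
#' s <- PhotonStream(channel = c(12L, 0L, 25L), tAbsNs = c(10, 250, 300),
#'                   microtimeNs = c(1.5, NA, 3.25))
#' writeEventList(s, f)
#' identical(nPhotons(readEventList(f)), 3L)
#' @name event-list-io
NULL

.FORMAT_MAGIC <- "#photonFFS-eventlist v1"

.geometryToList <- function(g) {
  list(nRows = g@nRows, nCols = g@nCols, pitchSampleNm = g@pitchSampleNm,
       waists = as.list(g@waists), eccentricities = as.list(g@eccentricities))
}

.laserToList <- function(l) {
  list(repPeriodNs = l@repPeriodNs, irfSigmaNs = l@irfSigmaNs,
       irfOffsetNs = l@irfOffsetNs, wavelengthNm = as.list(l@wavelengthNm))
}

.scanToList <- function(s) {
  if (is.null(s)) return(NULL)
  list(mode = s@mode, pixelDwellUs = s@pixelDwellUs, nX = s@nX, nY = s@nY,
       pixelSizeNm = s@pixelSizeNm, radiusNm = s@radiusNm,
       periodUs = s@periodUs)
}

#' @rdname event-list-io
#' @export
writeEventList <- function(stream, path) {
  stopifnot(is(stream, "PhotonStream"))
  validObject(stream)
  meta <- list(
    geometry = .geometryToList(stream@geometry),
    laser = .laserToList(stream@laser),
    scan = .scanToList(stream@scan),
    durationS = stream@durationS,
    volume = stream@volume,
    nPhotons = nPhotons(stream))
  header <- c(.FORMAT_MAGIC,
              paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                                digits = NA, null = "null")),
              "channel\tt_abs_ns\tmicrotime_ps")
  writeLines(header, path)
  if (nPhotons(stream) > 0) {
    dt <- data.table::data.table(
      channel = stream@channel,
      t_abs_ns = round(stream@tAbsNs),
      microtime_ps = round(stream@microtimeNs * 1e3))
    data.table::fwrite(dt, path, sep = "\t", na = "", col.names = FALSE,
                       append = TRUE, scipen = 50L)
  }
  invisible(path)
}

#' @rdname event-list-io
#' @export
readEventList <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such event list: %s", path))
  head <- readLines(path, n = 3L)
  if (length(head) < 3L || head[1] != .FORMAT_MAGIC)
    stop(sprintf("malformed event list '%s': missing magic line '%s'",
                 path, .FORMAT_MAGIC))
  if (!startsWith(head[2], "#meta "))
    stop(sprintf("malformed event list '%s': missing #meta header", path))
  meta <- tryCatch(jsonlite::fromJSON(sub("^#meta ", "", head[2])),
                   error = function(e)
                     stop(sprintf("malformed event list '%s': bad metadata JSON (%s)",
                                  path, conditionMessage(e)), call. = FALSE))
  geom <- DetectorGeometry(
    nRows = meta$geometry$nRows, nCols = meta$geometry$nCols,
    pitchSampleNm = meta$geometry$pitchSampleNm,
    waists = unlist(meta$geometry$waists),
    eccentricities = unlist(meta$geometry$eccentricities))
  laser <- LaserConfig(
    repPeriodNs = meta$laser$repPeriodNs, irfSigmaNs = meta$laser$irfSigmaNs,
    irfOffsetNs = meta$laser$irfOffsetNs,
    wavelengthNm = unlist(meta$laser$wavelengthNm))
  scan <- if (is.null(meta$scan)) NULL else
    ScanMetadata(mode = meta$scan$mode, pixelDwellUs = meta$scan$pixelDwellUs,
                 nX = meta$scan$nX, nY = meta$scan$nY,
                 pixelSizeNm = meta$scan$pixelSizeNm,
                 radiusNm = meta$scan$radiusNm, periodUs = meta$scan$periodUs)
  nExpected <- meta$nPhotons
  if (is.null(nExpected)) nExpected <- NA_integer_
  emptyDt <- data.table::data.table(channel = integer(0),
                                    t_abs_ns = numeric(0),
                                    microtime_ps = numeric(0))
  dt <- if (identical(nExpected, 0L) || identical(nExpected, 0)) emptyDt else
    tryCatch(
      data.table::fread(path, sep = "\t", skip = 3L, header = FALSE,
                        col.names = c("channel", "t_abs_ns", "microtime_ps"),
                        colClasses = list(integer = 1L, numeric = 2:3),
                        na.strings = ""),
      error = function(e) {
        if (is.na(nExpected)) emptyDt else
          stop(sprintf("malformed event list '%s': %s", path,
                       conditionMessage(e)), call. = FALSE)
      })
  if (!is.na(nExpected) && nrow(dt) != nExpected)
    stop(sprintf("malformed event list '%s': %d records found, %d declared",
                 path, nrow(dt), nExpected))
  if (nrow(dt) > 0) {
    bad <- which(is.na(dt$channel) | is.na(dt$t_abs_ns))
    if (length(bad))
      stop(sprintf("malformed event list '%s': record %d has a missing/invalid %s",
                   path, bad[1],
                   if (is.na(dt$channel[bad[1]])) "channel" else "t_abs_ns"))
    maxCh <- geom@nRows * geom@nCols
    bad <- which(dt$channel < 0L | dt$channel > maxCh)
    if (length(bad))
      stop(sprintf("geometry mismatch in '%s': record %d has channel %d outside 0..%d",
                   path, bad[1], dt$channel[bad[1]], maxCh))
  }
  PhotonStream(channel = dt$channel, tAbsNs = as.numeric(dt$t_abs_ns),
               microtimeNs = dt$microtime_ps / 1e3, geometry = geom,
               laser = laser, scan = scan, durationS = meta$durationS,
               volume = if (is.null(meta$volume)) "" else meta$volume)
}

#' Export an intensity trace to CSV
#'
#' @param trace an [IntensityTrace-class].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
writeIntensityTrace <- function(trace, path) {
  dt <- data.table::data.table(
    t_us = trace@t0Us + (seq_along(trace@counts) - 1) * trace@binWidthUs,
    counts = trace@counts)
  data.table::fwrite(dt, path)
  invisible(path)
}
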