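#' Build the 4D photon-counting histogram of a raster scan
#'
#' Assigns every photon of a raster-scanned stream to (pixel, channel,
#' microtime bin) through the pixel dwell clock, producing the 4D
#' (y, x, channel, dt) histogram that image scanning microscopy
#' reconstruction operates on. Counts are conserved.
#'
#' @param stream a [PhotonStream-class] with raster [ScanMetadata-class].
#' @param microtimeBins number of microtime bins (1 collapses to
#'   intensity-only imaging).
#' @return An [ISMStack-class].
#' @export
buildStack <- function(stream, microtimeBins = 32) {
  scan <- stream@scan
  if (is.null(scan) || scan@mode != "raster")
    stop("buildStack needs a raster-scanned stream")
  nX <- scan@nX; nY <- scan@nY
  nCh <- stream@geometry@nRows * stream@geometry@nCols
  dwellNs <- scan@pixelDwellUs * 1e3
  arrayPh <- stream@channel < nCh
  ch <- stream@channel[arrayPh]
  pix <- floor(stream@tAbsNs[arrayPh] / dwellNs)
  bad <- sum(pix >= nX * nY | pix < 0)
  if (bad > 0)
    stop(sprintf(
      "scan clock inconsistency: %d photons fall outside the %d x %d frame",
      bad, nX, nY))
  m <- stream@microtimeNs[arrayPh]
  Trep <- stream@laser@repPeriodNs
  if (all(is.na(m))) microtimeBins <- 1L
  dt <- if (microtimeBins == 1L) rep(0L, length(ch)) else
    pmin(microtimeBins - 1L, floor((m %% Trep) / Trep * microtimeBins))
  x <- pix %% nX
  y <- pix %/% nX
  idx <- 1 + y + nY * (x + nX * (ch + nCh * dt))
  counts <- array(tabulate(idx, nbins = nY * nX * nCh * microtimeBins),
                  dim = c(nY, nX, nCh, microtimeBins))
  edges <- seq(0, Trep, length.out = microtimeBins + 1)
  new("ISMStack", counts = counts, pixelSizeNm = scan@pixelSizeNm,
      microtimeEdgesNs = edges, geometry = stream@geometry,
      laser = stream@laser)
}

# microtime-integrated per-channel images: (y, x, ch)
.stackChannelImages <- function(stack) {
  d <- dim(stack@counts)
  if (d[4] == 1L) return(array(stack@counts, dim = d[1:3]))
  apply(stack@counts, c(1, 2, 3), sum)
}

# channel-summed time cube: (y, x, dt)
.stackTimeCube <- function(stack) {
  d <- dim(stack@counts)
  if (d[3] == 1L) return(array(stack@counts, dim = d[c(1, 2, 4)]))
  apply(stack@counts, c(1, 2, 4), sum)
}

# Phase correlation of img against ref; returns the displacement (dy, dx)
# of img relative to ref and the normalized peak height. The normalized
# cross-power spectrum is tapered with a Gaussian low-pass before the
# inverse transform: pure phase correlation weights all frequencies
# equally, so for smooth, photon-noise-limited images the correlation
# surface is dominated by noise at frequencies carrying no signal; the
# taper concentrates the peak without biasing its (sub-pixel) position.
.phaseCorrelate <- function(ref, img, eps = 1e-12, taperSigmaPx = 3) {
  if (stats::sd(ref) == 0 || stats::sd(img) == 0)
    return(list(shift = c(0, 0), confidence = 0))
  Fr <- stats::fft(ref); Fi <- stats::fft(img)
  X <- Fr * Conj(Fi)
  R <- X / pmax(Mod(X), eps)
  n <- dim(R)
  freq <- function(m) {
    f <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
    exp(-2 * pi^2 * taperSigmaPx^2 * f^2)
  }
  W <- outer(freq(n[1]), freq(n[2]))
  R <- R * W
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R) / mean(W)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- dim(r)
  # sub-pixel refinement: quadratic interpolation around the peak, per axis
  refine <- function(axis) {
    i0 <- pk[axis]
    im <- if (i0 == 1) n[axis] else i0 - 1
    ip <- if (i0 == n[axis]) 1 else i0 + 1
    v0 <- r[pk[1], pk[2]]
    vm <- if (axis == 1) r[im, pk[2]] else r[pk[1], im]
    vp <- if (axis == 1) r[ip, pk[2]] else r[pk[1], ip]
    den <- vm - 2 * v0 + vp
    if (abs(den) < eps) 0 else 0.5 * (vm - vp) / den
  }
  pos <- (pk - 1) + c(refine(1), refine(2))
  pos <- ((pos + n / 2) %% n) - n / 2   # wrap to [-n/2, n/2)
  list(shift = -pos, confidence = max(r))
}

#' Register channel images into a shift-vector fingerprint
#'
#' Aligns every microtime-integrated channel image to the central element's
#' image by phase correlation with sub-pixel (quadratic) peak refinement
#' and stores the lateral shifts in a shift-vector fingerprint. Channels
#' with a low-confidence correlation peak (dim corner elements, featureless
#' images) fall back to the geometric expectation: a 2D linear model of the
#' confident shifts across the array.
#'
#' @param stack an [ISMStack-class].
#' @param minConfidence normalized peak height below which a channel falls
#'   back to the fitted fingerprint model.
#' @return A [ShiftFingerprint-class] (shifts in pixels, central element
#'   fixed at zero).
#' @export
registerChannels <- function(stack, minConfidence = 0.2) {
  imgs <- .stackChannelImages(stack)
  nCh <- dim(imgs)[3]
  geom <- stack@geometry
  central <- volumeChannels(geom, "central") + 1L
  ref <- imgs[, , central]
  shifts <- matrix(0, nCh, 2, dimnames = list(NULL, c("dy", "dx")))
  conf <- numeric(nCh)
  for (ch in seq_len(nCh)) {
    if (ch == central) { conf[ch] <- 1; next }
    pc <- .phaseCorrelate(ref, imgs[, , ch])
    shifts[ch, ] <- pc$shift
    conf[ch] <- pc$confidence
  }
  low <- conf < minConfidence
  low[central] <- FALSE
  if (any(low)) {
    if (sum(!low) >= 4) {
      row <- (seq_len(nCh) - 1) %/% geom@nCols
      col <- (seq_len(nCh) - 1) %% geom@nCols
      ok <- !low
      for (j in 1:2) {
        fitlm <- stats::lm(shifts[ok, j] ~ row[ok] + col[ok])
        shifts[low, j] <- stats::predict(
          fitlm, data.frame(row = row, col = col)[low, , drop = FALSE])
      }
    } else {
      # nearly featureless frame: no reliable fingerprint, fall back to
      # the open (unshifted) reconstruction for the low channels
      shifts[low, ] <- 0
    }
  }
  new("ShiftFingerprint", shifts = shifts, confidence = conf,
      lowConfidence = low)
}

# Translate image content by (dy, dx) pixels (bilinear, zero fill).
.translateBilinear <- function(img, dy, dx) {
  n <- dim(img)
  ys <- seq_len(n[1]) - dy
  xs <- seq_len(n[2]) - dx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= n[1]
    okx <- xx >= 1 & xx <= n[2]
    m <- matrix(0, n[1], n[2])
    if (any(ok) && any(okx))
      m[ok, okx] <- img[yy[ok], xx[okx], drop = FALSE]
    m
  }
  at(y0, x0) * outer(1 - fy, 1 - fx) +
    at(y0 + 1, x0) * outer(fy, 1 - fx) +
    at(y0, x0 + 1) * outer(1 - fy, fx) +
    at(y0 + 1, x0 + 1) * outer(fy, fx)
}

#' Reconstruct an ISM image by adaptive pixel reassignment
#'
#' Translates every channel image (per microtime bin when
#' `timeResolved = TRUE`) by the negated fingerprint shift and integrates
#' over the channel dimension, producing the reassigned, super-resolved
#' intensity image; a zero fingerprint reproduces the plain channel sum
#' ("open" image). Borders are cropped by the maximum shift magnitude.
#' Optionally derives a per-pixel lifetime map (FLISM) from the reassigned
#' time-resolved stack, by phasor inversion (`tau = s/(omega g)`) or by
#' per-pixel mono-exponential tail fits.
#'
#' @param stack an [ISMStack-class].
#' @param fingerprint a [ShiftFingerprint-class] (from
#'   [registerChannels()]).
#' @param timeResolved keep the reassigned (y, x, dt) stack.
#' @param lifetime `"none"`, `"phasor"` or `"fit"`.
#' @param minCounts pixels with fewer photons get `NA` lifetime.
#' @return An [ISMImage-class].
#' @export
reconstructISM <- function(stack, fingerprint, timeResolved = FALSE,
                           lifetime = c("none", "phasor", "fit"),
                           minCounts = 100) {
  lifetime <- match.arg(lifetime)
  d <- dim(stack@counts)
  if (nrow(fingerprint@shifts) != d[3])
    stop(sprintf("fingerprint has %d channels but the stack has %d",
                 nrow(fingerprint@shifts), d[3]))
  needCube <- timeResolved || lifetime != "none"
  nDt <- if (needCube) d[4] else 1L
  cube <- array(0, dim = c(d[1], d[2], nDt))
  chImgs <- if (!needCube) .stackChannelImages(stack) else NULL
  for (ch in seq_len(d[3])) {
    s <- fingerprint@shifts[ch, ]
    if (needCube) {
      for (b in seq_len(d[4])) {
        sl <- matrix(stack@counts[, , ch, b], d[1], d[2])
        cube[, , b] <- cube[, , b] + .translateBilinear(sl, -s[1], -s[2])
      }
    } else {
      cube[, , 1] <- cube[, , 1] +
        .translateBilinear(chImgs[, , ch], -s[1], -s[2])
    }
  }
  crop <- as.integer(ceiling(max(abs(fingerprint@shifts))))
  if (crop > 0 && d[1] > 2 * crop && d[2] > 2 * crop) {
    cube <- cube[(crop + 1):(d[1] - crop), (crop + 1):(d[2] - crop), ,
                 drop = FALSE]
  } else crop <- 0L
  intensity <- if (dim(cube)[3] == 1L) cube[, , 1] else
    apply(cube, c(1, 2), sum)

  lifetimeMap <- NULL
  if (lifetime != "none") {
    if (d[4] < 4) stop("lifetime maps need >= 4 microtime bins")
    lifetimeMap <- .lifetimeMapFromCube(cube, stack@microtimeEdgesNs,
                                        stack@laser@repPeriodNs, lifetime,
                                        minCounts)
  }
  new("ISMImage", intensity = intensity,
      timeResolved = if (timeResolved) cube else NULL,
      lifetimeMapNs = lifetimeMap, pixelSizeNm = stack@pixelSizeNm,
      cropPx = crop, fingerprint = fingerprint)
}

#' Read and write shift-vector fingerprints as structured text
#'
#' @param fingerprint a [ShiftFingerprint-class].
#' @param path TSV file path.
#' @return `writeFingerprint` invisibly returns `path`;
#'   `readFingerprint` the reconstructed [ShiftFingerprint-class].
#' @name fingerprint-io
#' @export
writeFingerprint <- function(fingerprint, path) {
  df <- data.frame(channel = seq_len(nrow(fingerprint@shifts)) - 1L,
                   dy = fingerprint@shifts[, 1],
                   dx = fingerprint@shifts[, 2],
                   confidence = fingerprint@confidence,
                   lowConfidence = fingerprint@lowConfidence)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname fingerprint-io
#' @export
readFingerprint <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  new("ShiftFingerprint",
      shifts = matrix(c(df$dy, df$dx), ncol = 2,
                      dimnames = list(NULL, c("dy", "dx"))),
      confidence = df$confidence, lowConfidence = df$lowConfidence)
}

.lifetimeMapFromCube <- function(cube, edgesNs, repPeriodNs, method,
                                 minCounts) {
  d <- dim(cube)
  totals <- apply(cube, c(1, 2), sum)
  out <- matrix(NA_real_, d[1], d[2])
  if (method == "phasor") {
    w <- 2 * pi / repPeriodNs
    tc <- (edgesNs[-1] + edgesNs[-length(edgesNs)]) / 2
    flat <- matrix(cube, nrow = d[1] * d[2])
    tot <- as.vector(totals)
    g <- as.vector(flat %*% cos(w * tc)) / tot
    s <- as.vector(flat %*% sin(w * tc)) / tot
    tau <- s / (w * g)
    tau[tot < minCounts | !is.finite(tau)] <- NA_real_
    out[] <- tau
  } else {
    idx <- which(totals >= minCounts)
    for (i in idx) {
      hist <- new("DecayHistogram", binEdgesNs = edgesNs,
                  counts = matrix(cube, nrow = d[1] * d[2])[i, ],
                  source = "pixel", repPeriodNs = repPeriodNs)
      ft <- tryCatch(fitMonoexp(hist), error = function(e) NULL)
      if (!is.null(ft)) out[i] <- ft@tauNs
    }
  }
  out
}
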