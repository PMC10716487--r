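# Independent oracles and small fixture builders shared across tests.

# Brute-force binned-trace correlator with symmetric normalization:
# the reference the photon-mode correlator must reproduce exactly at
# matching bin widths.
bruteForceG <- function(tNs, wNs, nBins, kBins, t0Ns = 0) {
  a <- as.numeric(tabulate(pmin(nBins, floor((tNs - t0Ns) / wNs) + 1),
                           nbins = nBins))
  vapply(kBins, function(k) {
    n <- nBins
    sab <- sum(a[1:(n - k)] * a[(k + 1):n])
    (n - k) * sab / (sum(a[1:(n - k)]) * sum(a[(k + 1):n])) - 1
  }, 0)
}

# Brute-force cross-correlation of two explicit traces.
bruteForceGTraces <- function(a, b, kBins) {
  vapply(kBins, function(k) {
    n <- length(a)
    sab <- sum(a[1:(n - k)] * b[(k + 1):n])
    (n - k) * sab / (sum(a[1:(n - k)]) * sum(b[(k + 1):n])) - 1
  }, 0)
}

# Stream with photons on a fixed set of channels/times.
tinyStream <- function(channel, tAbsNs, microtimeNs = rep(NA_real_,
                                                          length(tAbsNs)),
                       durationS = max(tAbsNs) / 1e9, ...) {
  PhotonStream(channel = as.integer(channel), tAbsNs = tAbsNs,
               microtimeNs = microtimeNs, durationS = durationS, ...)
}

# Photon stream of a homogeneous Poisson process on one channel.
poissonStream <- function(rateHz, durationS, seed = 1, channel = 12L) {
  set.seed(seed)
  n <- rpois(1, rateHz * durationS)
  tinyStream(rep(channel, n), sort(runif(n, 0, durationS * 1e9)),
             durationS = durationS)
}

# Full width at half maximum of a peaked image, via a 2D Gaussian fit.
imageFWHM <- function(img) {
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  y <- seq_len(nrow(img)); x <- seq_len(ncol(img))
  df <- expand.grid(y = y, x = x)
  df$z <- as.vector(img)
  start <- list(A = max(img), y0 = pk[1], x0 = pk[2], sig = 2,
                B = min(img))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) p$A * exp(-((df$y - p$y0)^2 + (df$x - p$x0)^2) /
                                 (2 * p$sig^2)) + p$B - df$z)
  2 * sqrt(2 * log(2)) * abs(fit$par$sig)
}

# Closed-form phasor of a mono-exponential decay.
phasorTheory <- function(tauNs, repPeriodNs, harmonic = 1) {
  w <- 2 * pi * harmonic / repPeriodNs
  c(g = 1 / (1 + (w * tauNs)^2), s = w * tauNs / (1 + (w * tauNs)^2))
}

# Raster-scanned single-bead stack (point-like emitter at frame centre).
beadStack <- function(seed = 1, n = 41, bright = 4e7, microtimeBins = 1) {
  b <- matrix(0, n, n); b[(n + 1) / 2, (n + 1) / 2] <- bright
  s <- simulateRasterScan(list(brightness = b, lifetimeNs = 2.5),
                          pixelSizeNm = 40, dwellUs = 50, seed = seed)
  buildStack(s, microtimeBins = microtimeBins)
}

# Binary disc mask.
discMask <- function(radiusPx, size = 2 * radiusPx + 21,
                     cy = (size + 1) / 2, cx = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size),
        function(y, x) (y - cy)^2 + (x - cx)^2 <= radiusPx^2)
}
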