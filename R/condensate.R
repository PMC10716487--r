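#' Particle (condensate) shape analysis on a segmented mask
#'
#' Labels connected components (8-connectivity), extracts a sub-pixel
#' boundary per particle (marching-squares isoline of the lightly smoothed
#' mask, so a digitized disc reaches circularity 1), and reports area,
#' perimeter, circularity `4 pi area / perimeter^2` and centroid.
#' Particles touching the image border are flagged (and typically excluded
#' from shape statistics).
#'
#' @param mask binary/logical matrix (or a label mask from
#'   [phasorSegment()], where a given label can be selected upstream).
#' @param pixelSizeNm pixel size (nm) for physical areas.
#' @param blurSigmaPx Gaussian pre-smoothing of the contour extraction
#'   (pixels).
#' @return A `data.frame` with one row per particle: `label`, `areaPx`
#'   (pixel count), `areaUm2` (sub-pixel contour area), `perimeterUm`,
#'   `circularity`, `centroidY`, `centroidX`, `touchesBorder`. An empty
#'   mask yields an empty table.
#' @export
particleAnalysis <- function(mask, pixelSizeNm = 50, blurSigmaPx = 0.8) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  empty <- data.frame(label = integer(0), areaPx = integer(0),
                      areaUm2 = numeric(0), perimeterUm = numeric(0),
                      circularity = numeric(0), centroidY = numeric(0),
                      centroidX = numeric(0), touchesBorder = logical(0))
  if (!any(m > 0)) return(empty)
  labels <- EBImage::bwlabel(m)
  labels <- matrix(as.integer(labels), nrow(m), ncol(m))
  pxUm <- pixelSizeNm * 1e-3
  rows <- lapply(seq_len(max(labels)), function(lb) {
    px <- which(labels == lb, arr.ind = TRUE)
    touches <- any(px[, 1] %in% c(1L, nrow(m))) ||
      any(px[, 2] %in% c(1L, ncol(m)))
    pad <- 4L
    r0 <- max(1L, min(px[, 1]) - pad); r1 <- min(nrow(m), max(px[, 1]) + pad)
    c0 <- max(1L, min(px[, 2]) - pad); c1 <- min(ncol(m), max(px[, 2]) + pad)
    sub <- matrix(0, r1 - r0 + 1 + 2 * pad, c1 - c0 + 1 + 2 * pad)
    sub[pad + seq_len(r1 - r0 + 1), pad + seq_len(c1 - c0 + 1)] <-
      (labels[r0:r1, c0:c1] == lb)
    sub <- .gblur(sub, blurSigmaPx)
    cl <- grDevices::contourLines(x = seq_len(nrow(sub)),
                                  y = seq_len(ncol(sub)), z = sub,
                                  levels = 0.5)
    if (!length(cl)) return(NULL)
    lens <- vapply(cl, function(cc) length(cc$x), 0L)
    cc <- cl[[which.max(lens)]]
    xs <- cc$x; ys <- cc$y
    if (xs[1] != xs[length(xs)] || ys[1] != ys[length(ys)]) {
      xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
    }
    per <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    area <- abs(sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)])) / 2
    data.frame(label = lb, areaPx = nrow(px), areaUm2 = area * pxUm^2,
               perimeterUm = per * pxUm,
               circularity = 4 * pi * area / per^2,
               centroidY = mean(px[, 1]), centroidX = mean(px[, 2]),
               touchesBorder = touches)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

# small separable Gaussian blur (zero-padded edges)
.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad <- function(mat, n) rbind(matrix(0, n, ncol(mat)), mat,
                                matrix(0, n, ncol(mat)))
  conv1 <- function(mat) {
    p <- pad(mat, r)
    out <- matrix(0, nrow(mat), ncol(mat))
    for (i in seq_along(k))
      out <- out + k[i] * p[(i - 1) + seq_len(nrow(mat)), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' k-means clustering with elbow selection of k
#'
#' Standardizes the feature columns (z-score; the clustered quantities mix
#' units such as um^2/s, dimensionless ratios and ns), runs k-means with
#' multiple restarts for each candidate k, and selects k by the elbow of
#' the within-cluster inertia curve: the candidate with maximal
#' perpendicular distance to the chord of the normalized curve, demoted to
#' k = 1 when even the best split retains more than `flatFraction` of the
#' k = 1 inertia. Deterministic under a fixed seed; labels are
#' canonicalized by centroid order.
#'
#' @param points numeric matrix (observations x features), e.g.
#'   (D, S_conf) or (D, S_conf, tau_fl).
#' @param kMax largest candidate k (needs `nrow(points) > kMax`).
#' @param standardize z-score features before clustering.
#' @param seed RNG seed for the restarts.
#' @param nstart k-means restarts.
#' @param flatFraction inertia fraction above which the elbow is rejected
#'   and k = 1 returned (a single Gaussian cloud retains ~40-70% of its
#'   inertia under any split; well-separated clusters drop below 20%).
#' @return A [ClusterResult-class] with per-cluster covariance confidence
#'   ellipses (on the original feature scale).
#' @export
kmeansElbow <- function(points, kMax = 6, standardize = TRUE, seed = 1,
                        nstart = 10, flatFraction = 0.3) {
  points <- as.matrix(points)
  if (nrow(points) <= kMax)
    stop(sprintf("need more than kMax = %d points", kMax))
  if (all(apply(points, 2, stats::sd) < 1e-12))
    stop("degenerate input: all points identical")
  x <- if (standardize) {
    sds <- apply(points, 2, stats::sd); sds[sds < 1e-12] <- 1
    scale(points, scale = sds)
  } else points

  .withSeed(seed, {
    inertia <- vapply(seq_len(kMax), function(k)
      stats::kmeans(x, centers = k, nstart = nstart,
                    iter.max = 100)$tot.withinss, 0)
    kBest <- 1L
    if (kMax >= 2 && inertia[1] > 0) {
      kn <- (seq_len(kMax) - 1) / (kMax - 1)
      iN <- (inertia - inertia[kMax]) / max(inertia[1] - inertia[kMax], 1e-12)
      # distance to the chord from (0, 1) to (1, 0)
      dist <- abs(kn + iN - 1) / sqrt(2)
      kBest <- which.max(dist)
      if (inertia[kBest] / inertia[1] > flatFraction) kBest <- 1L
    }
    km <- stats::kmeans(x, centers = kBest, nstart = nstart, iter.max = 100)
    ord <- do.call(order, as.data.frame(km$centers))
    relabel <- match(seq_len(kBest), ord)
    assign <- relabel[km$cluster]
    centers <- km$centers[ord, , drop = FALSE]
    if (standardize) {
      mu <- attr(x, "scaled:center"); sdv <- attr(x, "scaled:scale")
      centers <- sweep(sweep(centers, 2, sdv, "*"), 2, mu, "+")
    }
    ell <- lapply(seq_len(kBest), function(cl) {
      pts <- points[assign == cl, , drop = FALSE]
      if (nrow(pts) >= 3 && ncol(pts) >= 2)
        tryCatch(confidenceEllipse(pts[, 1:2, drop = FALSE]),
                 error = function(e) NULL)
      else NULL
    })
    new("ClusterResult", k = as.integer(kBest),
        assignments = as.integer(assign), centroids = centers,
        inertia = inertia, ellipses = ell,
        standardized = isTRUE(standardize))
  })
}

#' Covariance confidence ellipse of a 2D point cloud
#'
#' Ellipse from the eigen-decomposition of the sample covariance, scaled
#' by the chi-square(2) quantile at the requested level, together with
#' Pearson's correlation coefficient. For a bivariate normal cloud the
#' ellipse contains the nominal fraction of the points.
#'
#' @param points n x 2 matrix (n >= 3).
#' @param level confidence level (default 0.95).
#' @return List with `center`, `radii` (semi-axes), `angleRad`, `pearson`,
#'   `level` and a `degenerate` flag (singular covariance).
#' @export
confidenceEllipse <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  if (ncol(points) != 2) stop("points must be n x 2")
  ctr <- colMeans(points)
  S <- stats::cov(points)
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- !is.finite(r) || abs(r) > 1 - 1e-9 ||
    ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300)
  q <- stats::qchisq(level, df = 2)
  radii <- sqrt(pmax(ev$values, 0) * q)
  list(center = ctr, radii = radii,
       angleRad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       pearson = r, level = level, degenerate = degenerate)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Welch-Satterthwaite degrees of freedom, at
#' a 0.95 confidence level. When both samples have zero variance the test
#' is defined by convention: p = 1 for equal means, p = 0 otherwise.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @return List with `statistic`, `df`, `pValue`, `significant`
#'   (p < 0.05) and `meanDiff`.
#' @export
welchTtest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    d <- mean(a) - mean(b)
    if (d == 0)
      return(list(statistic = 0, df = length(a) + length(b) - 2, pValue = 1,
                  significant = FALSE, meanDiff = 0))
    return(list(statistic = sign(d) * Inf,
                df = length(a) + length(b) - 2, pValue = 0,
                significant = TRUE, meanDiff = d))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, significant = tt$p.value < 0.05,
       meanDiff = unname(diff(rev(tt$estimate))))
}
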