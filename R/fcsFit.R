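#' FCS model curves
#'
#' `fcs3DModel` is the 1-component 3D-Gaussian diffusion model
#' `G(tau) = offset + (1/N) (1 + tau/tauD)^-1 (1 + tau/(k^2 tauD))^-1/2`;
#' the geometric gamma factor is folded into the fitted amplitude `1/N`.
#' `fcsScanModel` multiplies the diffusive part by the circular-scanning
#' factor `exp(-4 R^2 sin^2(pi tau / T) / (omega0^2 (1 + tau/tauD)))`,
#' which reduces exactly to the static model at `R = 0` and makes the
#' focal-spot size identifiable without assuming a diffusion coefficient.
#'
#' @param tauS lag times (s).
#' @param N mean occupancy (amplitude `1/N`).
#' @param tauDS diffusion time (s).
#' @param k axial eccentricity of the detection volume.
#' @param offset baseline offset.
#' @param fraction fast-component fraction (2-component model).
#' @param tauD2S slow-component diffusion time (s).
#' @param omega0Nm lateral waist (nm).
#' @param radiusNm,periodUs circular-scan radius (nm) and period (us).
#' @return Model values of `G(tau)`.
#' @export
fcs3DModel <- function(tauS, N, tauDS, k, offset = 0) {
  offset + (1 / N) / ((1 + tauS / tauDS) * sqrt(1 + tauS / (k^2 * tauDS)))
}

#' @rdname fcs3DModel
#' @export
fcs3DModel2 <- function(tauS, N, tauDS, tauD2S, fraction, k, offset = 0) {
  offset + (1 / N) *
    (fraction / ((1 + tauS / tauDS) * sqrt(1 + tauS / (k^2 * tauDS))) +
     (1 - fraction) / ((1 + tauS / tauD2S) *
                       sqrt(1 + tauS / (k^2 * tauD2S))))
}

#' @rdname fcs3DModel
#' @export
fcsScanModel <- function(tauS, N, tauDS, k, offset, omega0Nm, radiusNm,
                         periodUs) {
  g <- (1 / N) / ((1 + tauS / tauDS) * sqrt(1 + tauS / (k^2 * tauDS)))
  scanArg <- 4 * radiusNm^2 * sin(pi * tauS / (periodUs * 1e-6))^2 /
    (omega0Nm^2 * (1 + tauS / tauDS))
  offset + g * exp(-scanArg)
}

# Weights from replicate scatter (inverse variance of the mean), if any.
.curveWeights <- function(curve) {
  reps <- curve@replicates
  if (is.null(reps) || ncol(reps) < 3) return(rep(1, length(curve@G)))
  v <- apply(reps, 1, stats::var) / ncol(reps)
  v[!is.finite(v) | v <= 0] <- NA
  v[is.na(v)] <- max(v, na.rm = TRUE)
  1 / v
}

# tauD initializer: lag where G falls to half its low-lag plateau.
.initTauD <- function(lagsS, G, offset = 0) {
  g0 <- stats::median(G[seq_len(min(3, length(G)))]) - offset
  if (!is.finite(g0) || g0 <= 0) return(stats::median(lagsS))
  half <- offset + g0 / 2
  below <- which(G <= half)
  if (!length(below)) return(lagsS[length(lagsS)] / 2)
  lagsS[below[1]]
}

.lmFit <- function(residFun, start, lower, upper) {
  fit <- minpack.lm::nls.lm(par = start, fn = residFun, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-12, ftol = 1e-12))
  if (fit$info == 0 || fit$info == 9)
    stop(sprintf(
      "FCS fit did not converge (info %d, chi^2 %.4g, last iterate: %s)",
      fit$info, fit$deviance,
      paste(sprintf("%s=%.4g", names(fit$par), unlist(fit$par)),
            collapse = ", ")))
  fit
}

.lmSe <- function(fit) {
  p <- length(fit$par)
  dof <- length(fit$fvec) - p
  covm <- tryCatch(solve(fit$hessian) * fit$deviance / max(1, dof),
                   error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(0, diag(covm)))
  names(se) <- names(fit$par)
  se
}

#' Fit an FCS model to a correlation curve
#'
#' Weighted least-squares fit of the 1- or 2-component 3D-Gaussian
#' diffusion model. Weights are the inverse replicate variance when the
#' curve carries at least three chunk replicates, otherwise unweighted.
#' The focal-spot size is conventionally held fixed at its calibrated
#' value (see [calibrateCircularFCS()]); the diffusion coefficient is
#' derived as `D = omega0^2 / (4 tauD)` per component.
#'
#' For 2-component fits, three perturbed starts are tried and the best
#' chi-square kept; components are ordered `tauD(fast) < tauD(slow)`.
#'
#' @param curve a [CorrelationCurve-class].
#' @param omega0Nm calibrated lateral waist (nm), fixed.
#' @param k axial eccentricity, fixed (4.5 central, 4.1 summed volumes).
#' @param nComponents 1 or 2.
#' @param start optional named list of start values
#'   (`N`, `tauDS`, `tauD2S`, `fraction`, `offset`).
#' @param fixed named numeric of parameters to hold fixed (any of the
#'   start names).
#' @param useWeights use replicate-based weights when available. With few
#'   chunk replicates the empirical variances are noisy and can destabilize
#'   the fit; the svFCS pipeline therefore defaults to unweighted fits.
#' @param lagMaxFactor restrict the fit to lags up to this multiple of the
#'   initial diffusion-time estimate (`Inf` fits the whole grid). The far
#'   tail of a measured curve carries little shape information but
#'   correlated noise.
#' @return An [FCSFit-class].
#' @examples
#' lag <- lagDesign()
#' tau <- 10^seq(-6, 0, by = 1 / 8)
#' g <- fcs3DModel(tau, N = 10, tauDS = 1e-3, k = 4.5)
#' cv <- new("CorrelationCurve", lagsS = tau, G = g, replicates = NULL,
#'           nChunksUsed = 1L, nChunksTotal = 1L, kind = "auto",
#'           volumes = "central")
#' fitFCS(cv, omega0Nm = 276, k = 4.5)
#' @export
fitFCS <- function(curve, omega0Nm, k = 4.1, nComponents = 1, start = NULL,
                   fixed = numeric(0), useWeights = TRUE,
                   lagMaxFactor = 30) {
  ok <- is.finite(curve@G) & is.finite(curve@lagsS)
  lagsS <- curve@lagsS[ok]; G <- curve@G[ok]
  w <- if (useWeights) .curveWeights(curve)[ok] else rep(1, sum(ok))
  nComponents <- as.integer(nComponents)
  stopifnot(nComponents %in% c(1L, 2L))

  if (is.finite(lagMaxFactor)) {
    tauInit <- if (!is.null(start) && !is.null(start$tauDS))
      max(unlist(start[intersect(names(start), c("tauDS", "tauD2S"))]))
    else .initTauD(lagsS, G) * (if (nComponents == 2) 10 else 1)
    lagMax <- max(lagMaxFactor * tauInit, lagsS[min(12, length(lagsS))])
    keep <- lagsS <= lagMax
    lagsS <- lagsS[keep]; G <- G[keep]; w <- w[keep]
  }

  parNames <- if (nComponents == 1) c("N", "tauDS", "offset") else
    c("N", "tauDS", "tauD2S", "fraction", "offset")
  tau0 <- .initTauD(lagsS, G)
  g0 <- max(stats::median(G[seq_len(min(3, length(G)))]), 1e-6)
  defaults <- list(N = 1 / g0, tauDS = tau0, tauD2S = tau0 * 10,
                   fraction = 0.5, offset = 0)
  if (!is.null(start)) defaults[names(start)] <- start
  free <- setdiff(parNames, names(fixed))
  if (length(G) <= length(free))
    stop(sprintf("curve has %d usable points for %d free parameters",
                 length(G), length(free)))

  lowerAll <- c(N = 1e-9, tauDS = min(lagsS) / 100, tauD2S = min(lagsS) / 100,
                fraction = 0, offset = -Inf)
  upperAll <- c(N = Inf, tauDS = max(lagsS) * 100, tauD2S = max(lagsS) * 100,
                fraction = 1, offset = Inf)

  modelFun <- function(p) {
    full <- c(p, fixed)
    if (nComponents == 1)
      fcs3DModel(lagsS, full[["N"]], full[["tauDS"]], k, full[["offset"]])
    else
      fcs3DModel2(lagsS, full[["N"]], full[["tauDS"]], full[["tauD2S"]],
                  full[["fraction"]], k, full[["offset"]])
  }
  sw <- sqrt(w)
  residFun <- function(p) sw * (modelFun(p) - G)

  starts <- list(unlist(defaults[free]))
  if (nComponents == 2) {
    s2 <- unlist(defaults[free]); s3 <- unlist(defaults[free])
    if ("tauDS" %in% free) s2["tauDS"] <- s2["tauDS"] / 5
    if ("tauD2S" %in% free) s2["tauD2S"] <- s2["tauD2S"] * 5
    if ("fraction" %in% free) s3["fraction"] <- 0.2
    if ("tauD2S" %in% free) s3["tauD2S"] <- s3["tauD2S"] * 2
    starts <- list(starts[[1]], s2, s3)
  }
  best <- NULL
  for (s in starts) {
    f <- tryCatch(.lmFit(residFun, as.list(s), lowerAll[free], upperAll[free]),
                  error = function(e) e)
    if (inherits(f, "error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("FCS fit did not converge from any start")

  est <- unlist(best$par); se <- .lmSe(best)
  allEst <- c(est, fixed)[parNames]
  allSe <- se[parNames]; names(allSe) <- parNames
  allSe[is.na(allSe)] <- 0
  # canonical component order: fast first
  if (nComponents == 2 && allEst[["tauDS"]] > allEst[["tauD2S"]]) {
    swp <- function(x) { x[c("tauDS", "tauD2S")] <- x[c("tauD2S", "tauDS")]; x }
    allEst <- swp(allEst); allSe <- swp(allSe)
    allEst[["fraction"]] <- 1 - allEst[["fraction"]]
  }
  wUm <- omega0Nm * 1e-3
  tauDs <- if (nComponents == 1) allEst[["tauDS"]] else
    c(fast = allEst[["tauDS"]], slow = allEst[["tauD2S"]])
  D <- wUm^2 / (4 * tauDs)
  tauSe <- if (nComponents == 1) allSe[["tauDS"]] else
    c(fast = allSe[["tauDS"]], slow = allSe[["tauD2S"]])
  DSe <- D * tauSe / tauDs
  dof <- max(1, length(G) - length(free))
  new("FCSFit", estimates = allEst, se = allSe,
      fixed = c(fixed, omega0Nm = omega0Nm, k = k), model = "3d",
      nComponents = nComponents, D = D, DSe = DSe,
      chisqRed = best$deviance / dof, lagsS = lagsS, G = G,
      fitted = modelFun(best$par), volume = curve@volumes[1])
}

#' Circular-scanning FCS calibration of the focal-spot size
#'
#' Fits the circular-scanning FCS model with the scan radius and period
#' held fixed while amplitude, diffusion time and focal-spot size are
#' fitted, yielding the calibrated waist `omega0` without assuming a
#' diffusion coefficient.
#'
#' @param curve a [CorrelationCurve-class] from a circular-scan
#'   acquisition.
#' @param radiusNm,periodUs known scan radius (nm) and period (us).
#' @param k axial eccentricity, fixed.
#' @param start optional named list of start values (`N`, `tauDS`,
#'   `omega0Nm`, `offset`).
#' @return An [FCSFit-class] with a fitted `omega0Nm` estimate.
#' @export
calibrateCircularFCS <- function(curve, radiusNm, periodUs, k = 4.1,
                                 start = NULL) {
  ok <- is.finite(curve@G) & is.finite(curve@lagsS)
  lagsS <- curve@lagsS[ok]; G <- curve@G[ok]
  w <- .curveWeights(curve)[ok]
  g0 <- max(stats::median(G[seq_len(min(3, length(G)))]), 1e-6)
  defaults <- list(N = 1 / g0, tauDS = .initTauD(lagsS, G),
                   omega0Nm = 300, offset = 0)
  if (!is.null(start)) defaults[names(start)] <- start
  sw <- sqrt(w)
  residFun <- function(p)
    sw * (fcsScanModel(lagsS, p[["N"]], p[["tauDS"]], k, p[["offset"]],
                       p[["omega0Nm"]], radiusNm, periodUs) - G)
  fit <- .lmFit(residFun, defaults,
                lower = c(1e-9, min(lagsS) / 100, 50, -Inf),
                upper = c(Inf, max(lagsS) * 100, 2000, Inf))
  est <- unlist(fit$par); se <- .lmSe(fit)
  wUm <- est[["omega0Nm"]] * 1e-3
  D <- wUm^2 / (4 * est[["tauDS"]])
  dof <- max(1, length(G) - length(est))
  new("FCSFit", estimates = est, se = se,
      fixed = c(radiusNm = radiusNm, periodUs = periodUs, k = k),
      model = "scan", nComponents = 1L, D = D,
      DSe = D * se[["tauDS"]] / est[["tauDS"]],
      chisqRed = fit$deviance / dof, lagsS = lagsS, G = G,
      fitted = fcsScanModel(lagsS, est[["N"]], est[["tauDS"]], k,
                            est[["offset"]], est[["omega0Nm"]], radiusNm,
                            periodUs),
      volume = curve@volumes[1])
}

.fitComponent <- function(fit, component = c("auto", "only", "fast", "slow")) {
  component <- match.arg(component)
  if (fit@nComponents == 1) {
    if (component %in% c("fast", "slow"))
      warning("1-component fit: using its only component")
    return(list(D = unname(fit@D[1]), DSe = unname(fit@DSe[1]),
                tauDS = fit@estimates[["tauDS"]],
                tauSe = fit@se[["tauDS"]], used = "only"))
  }
  if (component %in% c("auto", "slow"))
    list(D = unname(fit@D[["slow"]]), DSe = unname(fit@DSe[["slow"]]),
         tauDS = fit@estimates[["tauD2S"]], tauSe = fit@se[["tauD2S"]],
         used = "slow")
  else
    list(D = unname(fit@D[["fast"]]), DSe = unname(fit@DSe[["fast"]]),
         tauDS = fit@estimates[["tauDS"]], tauSe = fit@se[["tauDS"]],
         used = "fast")
}

#' Diffusion-law regression over nested detection volumes
#'
#' Ordinary least squares of the diffusion time on the squared focal-spot
#' size, `tauD = omega0^2/(4D) + t0`. The intercept classifies the motion:
#' within `z` standard errors of zero = free diffusion; significantly
#' positive = hopping or domain-confined diffusion; significantly negative
#' = diffusion through a meshwork. For 2-component fits the slow
#' (condensate-bound) component is used by default.
#'
#' @param fits list of [FCSFit-class] objects (>= 2 volumes).
#' @param component `"auto"` (slow for 2-component fits), `"only"`,
#'   `"fast"` or `"slow"`.
#' @param z significance multiple for the intercept classification
#'   (1.96 = 95%).
#' @param minInterceptFraction practical-equivalence floor: intercepts
#'   smaller than this fraction of the smallest diffusion time are
#'   classified as free regardless of their (3-point, 1-dof) standard
#'   error, which is easily over-confident.
#' @return A [DiffusionLawResult-class].
#' @export
diffusionLaw <- function(fits, component = "auto", z = 1.96,
                         minInterceptFraction = 0.02) {
  if (length(fits) < 2) stop("diffusion law needs at least 2 volumes")
  comps <- lapply(fits, .fitComponent, component = component)
  x <- vapply(fits, function(f) (f@fixed[["omega0Nm"]] * 1e-3)^2, 0)
  y <- vapply(comps, function(cc) cc$tauDS * 1e3, 0)      # ms
  ySe <- vapply(comps, function(cc) cc$tauSe * 1e3, 0)
  lmfit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(lmfit)$coefficients)
  t0 <- sm[1, 1]; t0Se <- sm[1, 2]
  slope <- sm[2, 1]; slopeSe <- sm[2, 2]
  # significance plus a practical-equivalence floor: tiny intercepts are
  # physically indistinguishable from free diffusion
  tol <- max(z * t0Se, minInterceptFraction * min(y), 1e-9 * max(abs(y)))
  cls <- if (t0 > tol) "hop_or_domain"
         else if (t0 < -tol) "meshwork" else "free"
  new("DiffusionLawResult", omega0SqUm2 = unname(x), tauDMs = unname(y),
      tauDSeMs = unname(ySe), slope = slope, slopeSe = slopeSe, t0Ms = t0,
      t0SeMs = t0Se, DLaw = 250 / slope,  # slope in ms/um^2 -> D in um^2/s
      motionClass = cls,
      volumes = vapply(fits, function(f) f@volume, ""))
}

#' Confinement strength
#'
#' Ratio of the diffusion coefficients measured with the smallest (central
#' element) and largest (sum 5x5) focal areas. 1 for free diffusion, < 1
#' for domain-confined motion, > 1 for meshwork-hindered motion. The error
#' is first-order propagated from the two fits.
#'
#' @param fitCentral,fitSum5x5 [FCSFit-class] objects of the two volumes.
#' @param component component selection as in [diffusionLaw()].
#' @return A [ConfinementResult-class].
#' @export
confinementStrength <- function(fitCentral, fitSum5x5, component = "auto") {
  a <- .fitComponent(fitCentral, component)
  b <- .fitComponent(fitSum5x5, component)
  if (a$D <= 0 || b$D <= 0) stop("non-positive diffusion coefficient")
  s <- a$D / b$D
  se <- s * sqrt((a$DSe / a$D)^2 + (b$DSe / b$D)^2)
  new("ConfinementResult", sConf = s, se = se, componentUsed = a$used)
}

#' Relative cross-correlation amplitude
#'
#' Ratios of the fitted zero-lag cross-correlation amplitude to each
#' autocorrelation amplitude (offset-subtracted). The ratio relative to
#' the green signal, `Gx(0)/Gred(0)`, estimates the bound fraction of the
#' green species, and vice versa.
#'
#' @param autoGreen,autoRed,cross [FCSFit-class] objects from a
#'   simultaneous acquisition.
#' @return Named numeric `c(relToGreen, relToRed)`.
#' @export
relativeCCAmplitude <- function(autoGreen, autoRed, cross) {
  amp <- function(f) 1 / f@estimates[["N"]]
  ag <- amp(autoGreen); ar <- amp(autoRed); ax <- amp(cross)
  if (ag <= 0 || ar <= 0)
    stop("non-positive autocorrelation amplitude")
  c(relToGreen = unname(ax / ar), relToRed = unname(ax / ag))
}

#' Hydrodynamic diameter from the Stokes-Einstein relation
#'
#' `d = k_B T / (3 pi eta D)`.
#'
#' @param DUm2S diffusion coefficient (um^2/s).
#' @param temperatureK temperature (K).
#' @param viscosityMPaS dynamic viscosity (mPa s).
#' @return Diameter in nm.
#' @examples
#' round(stokesEinsteinDiameter(17.7, 293, 1.0))  # 24 nm
#' @export
stokesEinsteinDiameter <- function(DUm2S, temperatureK = 293,
                                   viscosityMPaS = 1.0) {
  stopifnot(DUm2S > 0, temperatureK > 0, viscosityMPaS > 0)
  kB <- 1.380649e-23
  dM <- kB * temperatureK /
    (3 * pi * viscosityMPaS * 1e-3 * DUm2S * 1e-12)
  dM * 1e9
}

#' Spot-variation FCS pipeline
#'
#' Convenience wrapper chaining channel merging, chunked correlation with
#' QC, per-volume 1-component fits with calibrated waists, the
#' diffusion-law regression and the confinement strength -- the standard
#' single-measurement svFCS analysis over the three nested detection
#' volumes.
#'
#' @param stream a raw multi-channel [PhotonStream-class].
#' @param chunkS chunk length (s).
#' @param design a [lagDesign()].
#' @param volumes named volumes to analyze.
#' @param nComponents components per fit.
#' @param component component feeding the diffusion law / S_conf.
#' @param fixed parameters held fixed in every fit. The baseline offset is
#'   fixed at 0 by default: chunked curves with symmetric normalization
#'   decay to a zero baseline, and fitting amplitude and diffusion time
#'   only (the calibrated waist being fixed anyway) is markedly more
#'   stable.
#' @param useWeights see [fitFCS()]; off by default (few replicates).
#' @return List with `fits`, `law` ([DiffusionLawResult-class]) and
#'   `confinement` ([ConfinementResult-class]).
#' @export
spotVariationFCS <- function(stream, chunkS = 10, design = lagDesign(),
                             volumes = c("central", "sum3x3", "sum5x5"),
                             nComponents = 1, component = "auto",
                             fixed = c(offset = 0), useWeights = FALSE) {
  geom <- stream@geometry
  fits <- lapply(volumes, function(v) {
    cv <- chunkedCorrelation(stream, chunkS = chunkS, design = design,
                             volume = v)
    fitFCS(cv, omega0Nm = geom@waists[[v]], k = geom@eccentricities[[v]],
           nComponents = nComponents, fixed = fixed,
           useWeights = useWeights)
  })
  names(fits) <- volumes
  law <- diffusionLaw(fits, component = component)
  conf <- if (all(c("central", "sum5x5") %in% volumes))
    confinementStrength(fits[["central"]], fits[["sum5x5"]],
                        component = component) else NULL
  list(fits = fits, law = law, confinement = conf)
}
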