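---
title: "photonFFS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{photonFFS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

photonFFS analyzes single-photon microscopy data from an asynchronous
read-out SPAD array detector (5x5 elements) plus an auxiliary
single-element detector. Every detected photon carries a channel index, an
absolute time (ns since experiment start) and a TCSPC microtime (start-stop
time within the laser period). From this one data structure the package
derives spot-variation FCS (svFCS), dual-color FCCS, fluorescence-lifetime
fits and phasors, and adaptive pixel-reassignment image scanning microscopy
(ISM/FLISM). A Brownian-dynamics photon-emission simulator stands in for
the instrument; all testing is simulator-based.

## The photon-stream data model

A `PhotonStream` holds time-ordered photon records together with the
detector geometry, laser configuration and (optional) scan metadata.
Channels 0-24 index the array row-major with the central element at 12;
channel 25 is the single-element detector. Streams persist in a
self-describing text container (versioned magic line, one JSON metadata
line, then TSV records with integer nanosecond absolute times and integer
picosecond microtimes; integer time columns avoid float drift over long
acquisitions).

Three nested virtual detection volumes are formed by merging channels:
the central element, the inner 3x3 block, and the whole array. Their
effective point-spread functions are modeled as 3D Gaussians with
calibrated 1/e^2 lateral waists of 276, 330 and 390 nm and axial
elongations k = 4.5 (central) and 4.1 (sums); the single-element detector
volume matches the sum 3x3 (330 nm). These are the values a
circular-scanning FCS calibration of the modeled instrument yields, and
the conventional FCS fits hold them fixed.

## The simulator

`simulatePhotonStream()` propagates point emitters through a periodic box
centred on the optical axis and draws photons from 3D-Gaussian detection
volumes:

* **Motion.** Free Brownian steps with per-axis variance `2 D dt`;
  a trap model (emitters toggle between free diffusion and confinement in
  a reflective spherical domain of configurable radius, entered at
  `trapRateS` and left at `escapeRateS`, with its own `dIn`); and a hop
  model (cubic meshwork of barriers crossed with probability
  `hopProbability`, otherwise reflected). The trap and hop
  parameterizations are this package's constructions; only their
  diffusion-law signatures (positive intercept and S_conf < 1 for domain
  confinement; hindered long-range transport for the meshwork) are
  anchored to the literature.
* **Detection (FCS mode).** Green photons are generated from the widest
  nested volume and assigned to channel sets by nested acceptance
  thinning, so that each merged volume is *exactly* a 3D Gaussian with its
  calibrated waist. Within the 3x3 and 5x5 rings photons are spread
  uniformly over the ring elements: channel merging, the only consumer of
  per-element identity in point measurements, is exact, while per-element
  spatial fidelity is deferred to the imaging mode. We chose this
  parameterization (rather than a grid of per-element Gaussians) because a
  grid of identical Gaussian element PSFs cannot reproduce all three
  calibrated nested waists simultaneously, whereas the analysis chain -
  like the real instrument's - is calibrated in terms of the effective
  nested volumes.
* **Detection (imaging mode).** `simulateRasterScan()` models each array
  element's effective PSF as the product of the excitation Gaussian and
  the element's laterally offset detection Gaussian: a narrowed Gaussian
  (width `omega/sqrt(2)` for equal widths) displaced by half the projected
  element offset. Per-element images of a phantom are therefore laterally
  shifted, slightly narrowed copies - precisely the property adaptive
  pixel reassignment exploits. The projected element pitch (not published
  for the modeled instrument) defaults to 175 nm, an array span of ~1.5
  Airy units; with Gaussian PSFs the ideal open-image/ISM width ratio is
  then `sqrt(1 + var(half-offsets)/sigma_PSF^2)` = 1.34.
* **Microtimes.** Exponential with the species lifetime, plus a Gaussian
  IRF (default sigma 0.1 ns, centre 2 ns), folded by the laser period
  (default 25 ns, i.e. 40 MHz; the repetition rate is configuration, not
  a published value).
* **Randomness.** One xoshiro256++ generator per simulation, seeded from the
  config; draws are consumed emitter by emitter, step by step, in the
  documented order (motion, state events, photon count, per-photon time /
  thinning / channel / microtime). Identical configuration and seed
  reproduce the stream bit for bit.

### Numerical accuracy choices

* **Time step.** Emission uses the position at the step start; the
  precondition `sqrt(2 D dt) < omega0/5` keeps the resulting smoothing far
  below shot noise. Defaults: 10 us for D ~ 10 um^2/s, reduced to 4-5 us
  for fast species (D > 100 um^2/s) and for circular scans (>= 200
  samples per scan revolution).
* **Box size.** Periodic boundaries quantize the diffusive relaxation
  spectrum: the slowest surviving concentration mode decays at
  `D (2 pi / L)^2`, so a finite box suppresses the correlation tail
  relative to the infinite-medium FCS model. Exact theta-function mode
  sums show that with L = 20x the central waist this biases the
  diffusion-law intercept by ~ +0.05 ms at D = 10 um^2/s - the same order
  as the effect being measured - while L = 40x leaves +0.006 ms, an order
  of magnitude below the statistical noise of a 60-s measurement. The
  default box is therefore 40x the central waist (11.04 um) per axis, with
  ~3 emitters/um^3 (about 1.6 in the central volume). Unit tests that
  only assert loose tolerances use 20x boxes for speed.
* **Far-field coarse stepping.** Freely diffusing emitters farther from
  the detection region than the emission cutoff plus five standard
  deviations of the aggregated displacement take 64x or 512x steps.
  Gaussian increments compose exactly, so free-motion statistics are
  unaffected; the guard band makes a missed emission excursion a
  < 1e-6-probability event. Disabled automatically for trap/hop motion
  and switchable off entirely.

The simulator deliberately does **not** emulate photophysics (blinking,
bleaching, saturation), detector dark counts, afterpulsing or crosstalk,
refractive-index aberrations, or cellular heterogeneity. Passing tests
therefore demonstrate correctness of the analysis chain under the stated
statistical model, not robustness to every artifact of real data - which
is why the curve-QC thresholds and calibration transforms stay
configurable.

## Correlation directly on photon times

`correlatePhotons()` bins the photon list at the base lag resolution
(default 1 us) and evaluates
`G(tau) = <dI_a(t) dI_b(t + tau)> / (<I_a> <I_b>)` with lag-proportional
coarsening: the bin width doubles once a lag exceeds 8 bins (multi-tau
scheme, default grid 8 points per decade from 1 us to 1 s). Normalization
is symmetric - means are taken over exactly the samples entering each lag's
products - which suppresses slow-drift bias and makes the result *exactly*
equal to a brute-force binned-trace correlation at matching bin widths
(a property the test suite asserts to 1e-6).

`chunkedCorrelation()` splits the stream into 5- or 10-s chunks,
correlates each independently, rejects artifact chunks, and averages the
survivors pointwise, keeping the replicates. The paper-style visual
curation is replaced by a deterministic QC: a chunk is rejected if its
mean intensity deviates more than 25% from the median chunk, or if its G
at the three smallest lags lies more than 5 robust standard deviations
(MAD) from the replicate median. Both thresholds are arguments.

## FCS model fitting

The 1-component 3D-Gaussian model is
`G(tau) = offset + (1/N) (1 + tau/tauD)^-1 (1 + tau/(k^2 tauD))^-1/2`,
with the geometric gamma factor folded into the fitted amplitude `1/N` (so
occupancy comparisons are internally consistent). The 2-component model is
the fraction-weighted sum with shared geometry; components are reported
fast-first. Fits use Levenberg-Marquardt with bounds; `tauD` is
initialized from the lag where G falls to half its plateau, `N` from the
plateau; 2-component fits run three perturbed starts and keep the best
chi-square.

Pipeline defaults, chosen after repeated-simulation stability studies:

* the baseline **offset is fixed at 0** (chunked, symmetrically normalized
  curves decay to a zero baseline; the instrument convention is to fit
  amplitude and diffusion times with the calibrated waist fixed);
* fits are **unweighted** - with only a handful of chunk replicates,
  empirical inverse-variance weights are noisy enough to destabilize
  `tauD`; replicate weights remain available via `useWeights = TRUE`;
* the fit window is restricted to lags up to **30x the initial tauD
  estimate** - the far tail carries correlated noise and no shape
  information.

`calibrateCircularFCS()` fits the circular-scanning model
`G_3D(tau) * exp(-4 R^2 sin^2(pi tau/T) / (omega0^2 (1 + tau/tauD)))`
with radius and period fixed, making the waist identifiable without
assuming a diffusion coefficient; at R = 0 it reduces exactly to the
static model. The scanning factor follows standard circular scanning-FCS
theory; the eccentricity enters only through the 3D factor.

`diffusionLaw()` regresses `tauD` on `omega0^2` by ordinary least squares
(`tauD = omega0^2/(4D) + t0`) and classifies the motion from the intercept
at z = 1.96: free when t0 is compatible with 0, hop/domain-confined when
significantly positive, meshwork when significantly negative. Because the
3-point regression SE has one degree of freedom and is easily
over-confident, a practical-equivalence floor applies: intercepts below
2% of the smallest diffusion time (configurable) are classified free
regardless of their nominal significance.
`confinementStrength()` is `D(central)/D(sum5x5)` with first-order error
propagation. For 2-component fits the slow (condensate-bound) component
feeds both by default - the dilute fast phase is the less informative one
for condensation - with the selection exposed.

`relativeCCAmplitude()` reports the fitted zero-lag cross-correlation
amplitude relative to each autocorrelation (offset-subtracted): the ratio
to the red autocorrelation estimates the bound fraction of the green
species and vice versa.

## Lifetime and phasors

Decay histograms use 256 uniform TCSPC bins over the laser period after
MOD-folding. `fitMonoexp()` performs a tail fit of `A exp(-t/tau) + B`
starting 0.5 ns after the histogram peak (IRF exclusion; no reconvolution
fitting). Phasors use harmonic 1, `omega = 2 pi / T_rep`; computed from
photon microtimes the folded-exponential expectation equals the closed
form `(g, s) = (1/(1+(w tau)^2), w tau/(1+(w tau)^2))` exactly, and from
histograms to bin-discretization accuracy. `calibratePhasor()` derives the
rotation + modulation scaling that maps a measured reference dye (e.g.
tau = 1 ns) onto its theoretical semicircle position; a provenance flag
refuses double application. One global calibration is applied; per-element
microtime offsets are not published for the modeled instrument and are
left configurable rather than defaulted.

Per-pixel phasor clouds keep pixels above 10% of the maximum pixel count
(configurable). `phasorSegment()` splits the cloud at the line through its
count-weighted centroid perpendicular to the g axis - left of the centroid
(smaller g) means longer lifetime - and back-projects both halves into
pixel masks; a custom projection axis is available. An all-identical cloud
is flagged degenerate and returned as a single label.

## ISM / FLISM reconstruction

`buildStack()` histograms a raster-scanned stream into (y, x, channel,
microtime) via the pixel dwell clock, with explicit diagnostics when
photons fall outside the declared frame. `registerChannels()` aligns the
microtime-integrated channel images to the central element by phase
correlation with sub-pixel quadratic peak refinement. The normalized
cross-power spectrum is tapered by a Gaussian low-pass (3 px) before the
inverse transform: flat spectral weighting is noise-dominated for smooth,
photon-limited images, and the taper concentrates the peak without
biasing its position (exact on constructed shifts). channels whose
normalized correlation peak is low (dim corner elements) fall back to a
2D linear model of the confident shifts across the array. One fingerprint
per frame is reused for all microtime bins, matching the reconstruction
convention of the modeled instrument. `reconstructISM()` translates every
channel (bilinear interpolation; Fourier shifting was considered and
rejected for its ringing on low-count images), sums over channels, and
crops the border by the maximum shift. A zero fingerprint reproduces the
plain channel sum, and photon counts are conserved up to the documented
crop (< 0.5% interpolation leakage for sub-pixel shifts). FLISM lifetime
maps come from the reassigned time cube either by phasor inversion
(`tau = s/(omega g)`, fast, default) or per-pixel tail fits.

## Condensate statistics

`particleAnalysis()` labels 8-connected components (EBImage) and measures
each particle on a sub-pixel contour: the 0.5-isoline (marching squares)
of the lightly Gaussian-smoothed mask. Area, perimeter and circularity
(`4 pi area / perimeter^2`) derive from the same contour, so a large
digitized disc reaches circularity 1 (boundary-pixel counting would
overestimate the perimeter by several percent); border-touching particles
are flagged for exclusion. `kmeansElbow()` z-scores the features (the
clustered quantities mix um^2/s, dimensionless ratios and ns; the raw
scale is also available), runs k-means with 10 restarts per candidate k,
and picks the elbow as the point of maximal perpendicular distance to the
chord of the normalized inertia curve - demoted to k = 1 when even the
best split keeps more than 30% of the single-cluster inertia (a single
Gaussian cloud retains ~40-70% under any split, well-separated clusters
drop below 20%), so single-population data are not force-split. Data with
three or more weakly separated groups can be demoted too; the threshold
is an argument. Labels are canonicalized by
centroid order, making results reproducible under a fixed seed.
`confidenceEllipse()` scales the covariance eigen-frame by the chi-square
(2 df) quantile; `welchTtest()` is the unequal-variance t-test at the 0.95
level, with the zero-variance corner cases fixed by convention (p = 1 for
identical constant samples, p = 0 otherwise).

## Problem sizes

The validation suite runs entirely on simulated data at desk scale: the
svFCS recovery conditions are a single 60-s stream at D = 10 um^2/s
(~9 M photons); circular-scan calibration uses 10-20 s at D = 17.7
um^2/s; the fast-monomer regime uses 15-30 s at D = 130 um^2/s; lifetime
recovery uses 1e5 microtimes; image-based checks use 33-48 px frames.
Property tests use 6-20-s streams in reduced (20x-waist) boxes with
correspondingly loose assertions.

### Statistical floor of the diffusion-law intercept

The intercept of a single spot-variation measurement is a small difference
of three correlated diffusion times, and its statistical noise is
dominated by the speckle term of FCS noise, which scales as
`sqrt(tauD / T_total)` and is independent of molecular brightness and
concentration (we verified both at 10x). For a 60-s measurement at
D = 10 um^2/s (tauD = 1.9-3.8 ms across the nested volumes) this floor is
about +/-0.05-0.1 ms and heavy-tailed; at the 2x faster nanosphere
diffusion it is correspondingly ~2x smaller. Single measurements near the
free/confined boundary therefore carry genuine classification
uncertainty, and the z = 1.96 test on the 3-point regression SE is
over-confident; replicate measurements (as any real study would use)
are the remedy. Estimator variants we evaluated on repeated simulations
(replicate-variance weights, floating baselines, restricted windows,
median-of-chunk fits, prewhitened difference fits) all sit at this floor,
which is why the defaults favour the simplest stable choice.

## Known limitations

* The analysis models assume 3D-Gaussian detection volumes; real SPAD
  array PSFs deviate in the wings, which is why waists are calibrated, not
  assumed.
* Tail fitting without IRF reconvolution biases lifetimes shorter than
  ~3x the IRF sigma; the default 0.5-ns peak offset is a compromise for
  nanosecond-scale dyes.
* The correlator's smallest meaningful lag is the base bin width (1 us by
  default); triplet/afterpulsing terms are out of scope.
* Chunk-QC thresholds are deterministic stand-ins for expert curation and
  should be reviewed for data with structured artifacts (e.g. slow
  drift that never crosses the intensity gate).
* 2-component fits on low-contrast mixtures (tauD ratio < ~3) are
  ill-conditioned, as in any FCS analysis.
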