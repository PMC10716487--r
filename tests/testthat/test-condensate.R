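test_that("particle analysis measures disc and square shapes correctly", {
  # ideal disc: circularity 1 within 3%
  disc <- discMask(100)
  tab <- particleAnalysis(disc, pixelSizeNm = 50)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$circularity, 1, tolerance = 0.03)
  expect_equal(tab$areaUm2, pi * (100 * 0.05)^2, tolerance = 0.02)

  # axis-aligned square: circularity pi/4
  sq <- matrix(FALSE, 140, 140); sq[21:120, 21:120] <- TRUE
  tabSq <- particleAnalysis(sq, pixelSizeNm = 50)
  expect_equal(tabSq$circularity, pi / 4, tolerance = 0.03)

  # two disjoint discs: two rows with the right areas and centroids
  two <- outer(seq_len(200), seq_len(320), function(y, x)
    ((y - 60)^2 + (x - 60)^2 <= 30^2) |
      ((y - 140)^2 + (x - 240)^2 <= 15^2))
  tab2 <- particleAnalysis(two, pixelSizeNm = 100)
  tab2 <- tab2[order(tab2$areaPx, decreasing = TRUE), ]
  expect_identical(nrow(tab2), 2L)
  expect_equal(tab2$areaPx[1] / (pi * 30^2), 1, tolerance = 0.02)
  expect_equal(tab2$areaPx[2] / (pi * 15^2), 1, tolerance = 0.05)

  # empty mask: empty table, not an error
  expect_identical(nrow(particleAnalysis(matrix(FALSE, 10, 10))), 0L)

  # border-touching particles are flagged
  edge <- matrix(FALSE, 50, 50); edge[1:10, 20:30] <- TRUE
  expect_true(particleAnalysis(edge)$touchesBorder)
})

test_that("circularity is invariant under rotation and scaling", {
  base <- discMask(40)
  cBase <- particleAnalysis(base)$circularity
  cBig <- particleAnalysis(discMask(120))$circularity
  expect_equal(cBase, cBig, tolerance = 0.02)

  # rotated ellipse keeps its circularity
  mkEllipse <- function(theta) {
    outer(seq_len(201), seq_len(201), function(y, x) {
      u <- (x - 101) * cos(theta) + (y - 101) * sin(theta)
      v <- -(x - 101) * sin(theta) + (y - 101) * cos(theta)
      (u / 70)^2 + (v / 35)^2 <= 1
    })
  }
  c0 <- particleAnalysis(mkEllipse(0))$circularity
  c45 <- particleAnalysis(mkEllipse(pi / 4))$circularity
  expect_equal(c45, c0, tolerance = 0.03)
  expect_lt(c0, 0.95)   # an ellipse is not a circle
})

test_that("k-means with elbow selection finds the cluster structure", {
  set.seed(1)
  blobs <- rbind(cbind(rnorm(60, 0), rnorm(60, 0)),
                 cbind(rnorm(60, 8), rnorm(60, 8)))
  truth <- rep(1:2, each = 60)
  res <- kmeansElbow(blobs, kMax = 6, seed = 5)
  expect_identical(res@k, 2L)
  acc <- max(mean(res@assignments == truth),
             mean(res@assignments == 3 - truth))
  expect_gt(acc, 0.95)

  # deterministic under a fixed seed
  res2 <- kmeansElbow(blobs, kMax = 6, seed = 5)
  expect_identical(res@assignments, res2@assignments)
  expect_equal(res@centroids, res2@centroids)

  # single blob: k = 1
  single <- cbind(rnorm(80), rnorm(80))
  expect_identical(kmeansElbow(single, kMax = 6, seed = 5)@k, 1L)

  expect_error(kmeansElbow(matrix(1, 30, 2), kMax = 4), "degenerate")
  expect_error(kmeansElbow(blobs[1:4, ], kMax = 6), "more than kMax")
})

test_that("svFCS feature clouds from distinct motion regimes split in two", {
  # stand-ins for pre-stress (free, fast) and post-stress (confined, slow)
  # pipeline outputs: (D, S_conf) pairs
  set.seed(2)
  pre <- cbind(D = rnorm(20, 2.3, 0.5), S = rnorm(20, 1.1, 0.15))
  post <- cbind(D = rnorm(20, 0.4, 0.15), S = rnorm(20, 0.6, 0.15))
  res <- kmeansElbow(rbind(pre, post), kMax = 5, seed = 3)
  expect_identical(res@k, 2L)
  lab <- res@assignments
  expect_true(all(lab[1:20] == lab[1]) && all(lab[21:40] == lab[21]))
  expect_false(lab[1] == lab[21])
  expect_identical(length(res@ellipses), 2L)
})

test_that("covariance confidence ellipses have the nominal geometry", {
  set.seed(4)
  iso <- cbind(rnorm(5000), rnorm(5000))
  e <- confidenceEllipse(iso, level = 0.95)
  r <- sqrt(qchisq(0.95, 2))
  expect_equal(unname(e$radii), c(r, r), tolerance = 0.05)
  expect_false(e$degenerate)
  expect_equal(e$pearson, 0, tolerance = 0.05)

  # coverage ~ 95% for a correlated bivariate normal
  S <- matrix(c(2, 1.2, 1.2, 1.5), 2)
  L <- chol(S)
  pts <- matrix(rnorm(2e4), ncol = 2) %*% L
  e2 <- confidenceEllipse(pts)
  ctr <- sweep(pts, 2, e2$center)
  R <- cbind(c(cos(e2$angleRad), sin(e2$angleRad)),
             c(-sin(e2$angleRad), cos(e2$angleRad)))
  u <- ctr %*% R
  inside <- (u[, 1] / e2$radii[1])^2 + (u[, 2] / e2$radii[2])^2 <= 1
  expect_equal(mean(inside), 0.95, tolerance = 0.01)

  # perfectly correlated cloud is degenerate
  x <- rnorm(50)
  e3 <- confidenceEllipse(cbind(x, 2 * x))
  expect_true(e3$degenerate)
  expect_error(confidenceEllipse(cbind(1:2, 1:2)), "at least 3")
})

test_that("Welch's t-test equals the hand formula and has power", {
  # identical samples: t = 0, p = 1
  r <- welchTtest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$pValue, 1)

  # textbook pair, checked against the explicit Welch formula
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r2 <- welchTtest(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tHand <- (mean(a) - mean(b)) / se
  dfHand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(r2$statistic, tHand, tolerance = 1e-12)
  expect_equal(r2$df, dfHand, tolerance = 1e-12)
  expect_equal(r2$pValue, 2 * pt(-abs(tHand), dfHand), tolerance = 1e-12)

  # zero-variance conventions
  expect_equal(welchTtest(c(1, 1), c(1, 1))$pValue, 1)
  expect_equal(welchTtest(c(1, 1), c(2, 2))$pValue, 0)

  # power: true lifetime difference 0.3 ns, sd 0.1, n = 20 per group
  set.seed(6)
  hits <- mean(vapply(1:200, function(i)
    welchTtest(rnorm(20, 2.3, 0.1), rnorm(20, 2.6, 0.1))$pValue < 0.05,
    TRUE))
  expect_gt(hits, 0.95)
})
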