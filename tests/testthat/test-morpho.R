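# Segmentation thresholds, 3D/2D morphometry, colocalization, dots and
# clusters. Brute-force threshold oracles are implemented independently
# here and compared against the package's histogram implementations.

bruteOtsu <- function(x, nbins = 256L) {
  # exhaustive search minimizing within-class variance
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  cnt <- tabulate(pmin(nbins, pmax(1L, findInterval(
    x, breaks, rightmost.closed = TRUE))), nbins)
  best <- Inf; bestK <- 1L
  for (k in 1:(nbins - 1L)) {
    c0 <- cnt[1:k]; c1 <- cnt[(k + 1L):nbins]
    if (sum(c0) == 0 || sum(c1) == 0) next
    m0 <- mids[1:k]; m1 <- mids[(k + 1L):nbins]
    v0 <- sum(c0 * (m0 - sum(c0 * m0) / sum(c0))^2)
    v1 <- sum(c1 * (m1 - sum(c1 * m1) / sum(c1))^2)
    if (v0 + v1 < best) { best <- v0 + v1; bestK <- k }
  }
  breaks[bestK + 1L]
}

test_that("global Otsu equals the exhaustive between-class optimum", {
  set.seed(42)
  for (i in 1:5) {
    x <- c(rnorm(400, 10, 2), rnorm(150 + 50 * i, 40, 5))
    expect_equal(mitoquant:::otsuThreshold(x), bruteOtsu(x),
                 tolerance = 1e-12)
  }
})

test_that("two-level stacks are segmented exactly", {
  cfg <- synthConfig(seed = 3, gaussianSD = 0)
  ms <- makeMitoStack(cfg, nObjects = 2, shape = "ellipsoid",
                      dim = c(64, 64, 24), cristae = "none",
                      objectIntensity = 200 / 255,
                      backgroundIntensity = 10 / 255)
  seg <- segmentMito(ms$stack, rollingBallRadiusPx = 20)
  truthFG <- ms$truth$masks[[1]] | ms$truth$masks[[2]]
  # threshold sits between the (background-subtracted) modes
  expect_lt(seg@thresholdGlobal, 190 / 255)
  expect_identical(seg@labels > 0, truthFG)
  expect_equal(max(seg@labels), 2)
})

test_that("single-voxel objects have exact volume and face area", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  seg <- segFromMask(m, voxelXYnm = 100, voxelZnm = 200)
  obj <- measure3D(seg)
  expect_equal(obj$volume_um3, 0.1 * 0.1 * 0.2)
  expect_equal(obj$surface_um2, 4 * 0.1 * 0.2 + 2 * 0.1 * 0.1)
})

test_that("digitized sphere volume is within 3% of 4/3 pi r^3", {
  m <- ellipsoidMask(c(31, 31, 31), c(16, 16, 16), c(10, 10, 10))
  obj <- measure3D(segFromMask(m))
  expect_equal(obj$volume_um3, 4 / 3 * pi, tolerance = 0.03)
  expect_equal(obj$branching, 1, tolerance = 0.05)
  expect_false(obj$truncated)
})

test_that("branching separates ellipsoids, tubes and branched tubes", {
  cfg <- synthConfig(seed = 3, voxelZnm = 65)
  mkBr <- function(shape) {
    ms <- makeMitoStack(cfg, nObjects = 1, shape = shape, cristae = "none",
                        dim = c(72, 72, 32))
    measure3D(segFromMask(ms$truth$masks[[1]], 65, 65))$branching
  }
  expect_gt(mkBr("ellipsoid"), 0.9)
  expect_lt(mkBr("ellipsoid"), 1.1)
  expect_lt(mkBr("branched"), mkBr("tube"))
})

test_that("per-object volumes conserve the foreground voxel count", {
  cfg <- synthConfig(seed = 12)
  ms <- makeMitoStack(cfg, nObjects = 3, dim = c(72, 72, 24))
  seg <- segmentMito(ms$stack, rollingBallRadiusPx = 20)
  objs <- measure3D(seg)
  voxVol <- (seg@voxelXYnm / 1000)^2 * (seg@voxelZnm / 1000)
  expect_equal(sum(objs$volume_um3), sum(seg@labels > 0) * voxVol,
               tolerance = 1e-12)
})

test_that("shape descriptors are rotation-robust", {
  ax <- c(12, 6, 6)
  ref <- measure3D(segFromMask(
    ellipsoidMask(c(41, 41, 41), rep(21, 3), ax)))
  for (th in c(pi / 2, pi / 5)) {
    rot <- measure3D(segFromMask(
      ellipsoidMask(c(41, 41, 41), rep(21, 3), ax, rotZ(th))))
    expect_equal(rot$elongation, ref$elongation, tolerance = 0.05)
    expect_equal(rot$flatness, ref$flatness, tolerance = 0.05)
  }
})

test_that("Pearson colocalization hits its analytic anchors", {
  set.seed(7)
  ch1 <- array(runif(10^5), c(100, 100, 10))
  expect_equal(pearsonColoc(ch1, ch1), 1)
  expect_equal(pearsonColoc(ch1, -ch1 + 3), -1)
  ch2 <- array(runif(10^5), c(100, 100, 10))
  expect_lt(abs(pearsonColoc(ch1, ch2)), 0.02)
  expect_error(pearsonColoc(ch1, array(1, dim(ch1))),
               "undefined_correlation")
})

test_that("MERCs product images equal direct multiplication", {
  a <- matrix(0, 20, 20); b <- matrix(0, 20, 20)
  a[1:10, ] <- 2; b[11:20, ] <- 3
  expect_true(all(mercsProductImage(a, b) == 0))  # disjoint supports
  b2 <- matrix(0, 20, 20); b2[5:15, ] <- 3
  prod <- mercsProductImage(a, b2, gain = 1)
  expect_equal(prod[7, 7], 6)
  g1 <- matrix(seq(0, 1, length.out = 400), 20, 20)
  g2 <- matrix(seq(1, 2, length.out = 400), 20, 20)
  expect_equal(mercsProductImage(g1, g2, gain = 2.5), g1 * g2 * 2.5)
})

test_that("2D morphology recovers circles and 2:1 ellipses", {
  disk <- diskMask(64, 32, 32, 14)
  obj <- measure2D(disk, pxNm = 100)
  expect_equal(nrow(obj), 1)
  expect_equal(obj$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(obj$area_um2, pi * 1.4^2, tolerance = 0.03)
  ell <- (row(matrix(0, 80, 80)) - 40)^2 / 24^2 +
    (col(matrix(0, 80, 80)) - 40)^2 / 12^2 <= 1
  obj2 <- measure2D(ell, pxNm = 100)
  expect_equal(obj2$aspect_ratio, 2, tolerance = 0.05)
})

test_that("Yen threshold equals the brute-force criterion maximum", {
  bruteYen <- function(x, nbins = 256L) {
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
    cnt <- tabulate(pmin(nbins, pmax(1L, findInterval(
      x, breaks, rightmost.closed = TRUE))), nbins)
    p <- cnt / sum(cnt)
    best <- -Inf; bestK <- 1L
    for (k in 1:(nbins - 1L)) {
      P1 <- sum(p[1:k]); P2 <- 1 - P1
      if (P1 <= 0 || P2 <= 0) next
      G1 <- sum(p[1:k]^2); G2 <- sum(p[(k + 1L):nbins]^2)
      crit <- -log(max(G1 * G2, 1e-300)) + 2 * log(max(P1 * P2, 1e-300))
      if (crit > best) { best <- crit; bestK <- k }
    }
    breaks[bestK + 1L]
  }
  set.seed(5)
  for (i in 1:4) {
    x <- c(rnorm(500, 20, 4), rnorm(100 * i, 60, 8))
    expect_equal(mitoquant:::yenThreshold(x), bruteYen(x), tolerance = 1e-12)
  }
})

test_that("PLA dot counting divides dots by nuclei and normalizes", {
  img <- matrix(0, 120, 120)
  nuc <- matrix(0, 120, 120)
  set.seed(3)
  # 30 dots of 4 px each on a 12x12 grid, 10 nuclei disks
  centers <- expand.grid(x = seq(10, 110, by = 20), y = seq(10, 110, by = 20))
  for (i in 1:30) {
    cx <- centers$x[i]; cy <- centers$y[i]
    img[cx + 0:1, cy + 0:1] <- 10
  }
  for (i in 1:10)
    nuc[diskMask(120, 12 * i - 5, 60, 4)] <- 50
  out <- countPlaDots(img, nuc, dotThreshold = 5)
  expect_equal(out$dots, 30)
  expect_equal(out$cells, 10)
  expect_equal(out$dots_per_cell, 3)
  # no supra-threshold pixels at all
  none <- countPlaDots(matrix(0, 120, 120), nuc, dotThreshold = 5)
  expect_equal(none$dots_per_cell, 0)
  # knockdown-like condition at 30% dot density normalizes to 0.3
  img30 <- matrix(0, 120, 120)
  for (i in 1:9) img30[centers$x[i] + 0:1, centers$y[i] + 0:1] <- 10
  kd <- countPlaDots(img30, nuc, dotThreshold = 5,
                     reference = out$dots_per_cell)
  expect_equal(kd$normalized, 0.3)
  expect_error(countPlaDots(img, matrix(0, 120, 120), 5), "no_cells")
})

test_that("cluster sizing finds disks and splits touching clusters", {
  img <- matrix(0, 80, 80)
  img[diskMask(80, 40, 40, 5)] <- 1
  out <- clusterSizes(img, sigmaPx = 0)
  expect_equal(nrow(out), 1)
  expect_equal(out$area_px2, sum(diskMask(80, 40, 40, 5)), tolerance = 0.15)
  img2 <- matrix(0, 80, 80)
  img2[diskMask(80, 35, 40, 6) | diskMask(80, 45, 40, 6)] <- 1
  out2 <- clusterSizes(img2, sigmaPx = 0)
  expect_equal(nrow(out2), 2)
})

test_that("Kapur threshold equals the brute-force entropy maximum", {
  bruteKapur <- function(x, nbins = 256L) {
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
    cnt <- tabulate(pmin(nbins, pmax(1L, findInterval(
      x, breaks, rightmost.closed = TRUE))), nbins)
    p <- cnt / sum(cnt)
    best <- -Inf; bestK <- 1L
    for (k in 1:(nbins - 1L)) {
      P1 <- sum(p[1:k]); P2 <- 1 - P1
      if (P1 <= 0 || P2 <= 0) next
      q1 <- p[1:k][p[1:k] > 0] / P1
      q2 <- p[(k + 1L):nbins][p[(k + 1L):nbins] > 0] / P2
      crit <- -sum(q1 * log(q1)) - sum(q2 * log(q2))
      if (crit > best) { best <- crit; bestK <- k }
    }
    breaks[bestK + 1L]
  }
  set.seed(9)
  for (i in 1:4) {
    x <- c(rnorm(600, 15, 3), rnorm(80 * i, 50, 6))
    expect_equal(mitoquant:::kapurThreshold(x), bruteKapur(x),
                 tolerance = 1e-9)
  }
})

test_that("segmentation is invariant to affine intensity rescaling", {
  cfg <- synthConfig(seed = 19)
  ms <- makeMitoStack(cfg, nObjects = 2, dim = c(64, 64, 20))
  seg1 <- segmentMito(ms$stack, rollingBallRadiusPx = 20)
  scaled <- new("ImageStack3D",
                channels = list(mito = ms$stack@channels$mito * 3.7 + 11),
                voxelXYnm = 65, voxelZnm = 200, frameIntervalS = NA_real_)
  seg2 <- segmentMito(scaled, rollingBallRadiusPx = 20)
  agree <- mean((seg1@labels > 0) == (seg2@labels > 0))
  expect_gt(agree, 0.999)
})
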