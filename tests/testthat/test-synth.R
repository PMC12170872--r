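# Synthetic generators: determinism, ground-truth fidelity, and the physical
# conventions the downstream modules rely on.

test_that("the same seed reproduces every generator bit-for-bit", {
  cfg <- synthConfig(seed = 11)
  a <- makeMitoStack(cfg, nObjects = 2, dim = c(48, 48, 20))
  b <- makeMitoStack(cfg, nObjects = 2, dim = c(48, 48, 20))
  expect_identical(a$stack@channels, b$stack@channels)
  expect_identical(a$truth$centres, b$truth$centres)
  expect_identical(makeTraceSet(cfg, nCells = 3)$traces[[2]]@chNum,
                   makeTraceSet(cfg, nCells = 3)$traces[[2]]@chNum)
  p1 <- makePatchSweeps(cfg, nPatches = 1, sweepsPerPotential = 1)
  p2 <- makePatchSweeps(cfg, nPatches = 1, sweepsPerPotential = 1)
  expect_identical(p1$recordings[[1]]@sweeps, p2$recordings[[1]]@sweeps)
  expect_identical(makeGoldField(cfg, nParticles = 50)$field@particles,
                   makeGoldField(cfg, nParticles = 50)$field@particles)
})

test_that("generator substreams are independent of each other", {
  cfg <- synthConfig(seed = 11)
  t1 <- makeTraceSet(cfg, nCells = 2)$traces[[1]]@chNum
  invisible(makeMitoStack(cfg, nObjects = 1, dim = c(48, 48, 20)))
  t2 <- makeTraceSet(cfg, nCells = 2)$traces[[1]]@chNum
  expect_identical(t1, t2)
})

test_that("ellipsoid stacks match the analytic mask and carry geometry", {
  cfg <- synthConfig(seed = 3)
  ms <- makeMitoStack(cfg, nObjects = 1, shape = "ellipsoid",
                      shapeParams = list(axes = c(10, 5, 5)),
                      dim = c(64, 64, 24))
  m <- ms$truth$masks[[1]]
  ctr <- ms$truth$centres[[1]]
  analytic <- ellipsoidMask(dim(m), ctr, c(10, 5, 5))
  expect_identical(m, analytic)
  # objects never touch the stack border
  expect_false(any(m[c(1, 64), , ]) || any(m[, c(1, 64), ]) ||
                 any(m[, , c(1, 24)]))
  expect_equal(unname(voxelSize(ms$stack)), c(65, 200))
  # z-step default mirrors 0.2 um confocal increments
  expect_equal(cfg@voxelZnm, 200)
  expect_equal(cfg@temPxNm, 2.94)
})

test_that("uniform cristae texture is radially flat, central is not", {
  cfg <- synthConfig(seed = 9)
  radialHalves <- function(cristae) {
    ms <- makeMitoStack(cfg, nObjects = 1, shape = "ellipsoid",
                        shapeParams = list(axes = c(12, 8, 8)),
                        dim = c(64, 64, 32), cristae = cristae)
    m <- ms$truth$masks[[1]]; cm <- ms$truth$cristaeMasks[[1]]
    idx <- which(m); co <- arrayInd(idx, dim(m))
    r <- sqrt(rowSums(sweep(co, 2, colMeans(co))^2))
    inner <- r <= median(r); outer <- !inner
    c(mean(cm[idx][inner]), mean(cm[idx][outer]))
  }
  u <- radialHalves("uniform")
  expect_lt(abs(u[1] - u[2]) / mean(u), 0.10)
  cen <- radialHalves("central")
  expect_gt(cen[1], 2 * cen[2])
})

test_that("overcrowded placement fails loudly", {
  cfg <- synthConfig(seed = 1)
  expect_error(makeMitoStack(cfg, nObjects = 50, dim = c(40, 40, 16)),
               "placement_failed")
})

test_that("null-transient and no-bleach traces behave as stated", {
  cfg <- synthConfig(seed = 4, gaussianSD = 0.02)
  flat <- makeTraceSet(cfg, kinetics = list(baseline = 1, bleach_tau = Inf,
                                            transient_amp = 0, t_on = 150,
                                            decay = 30), nCells = 3)
  for (tr in flat$traces) {
    # stationary channels: no trend beyond noise
    sl <- coef(lm(tr@chNum ~ tr@timeS))[2]
    expect_lt(abs(sl) * max(tr@timeS), 3 * sd(tr@chNum))
    rt <- computeRatio(tr)
    expect_lt(rt@delta, 4 * sd(rt@ratio[rt@baselineWindow]))
    expect_equal(rt@basal, 1, tolerance = 0.02)
  }
})

test_that("generated bleach decay is recovered within 5% at SNR 20", {
  cfg <- synthConfig(seed = 6, gaussianSD = 0.05)
  ts <- makeTraceSet(cfg, nCells = 20)
  basal <- 1:75  # the full pre-stimulus phase
  taus <- sapply(ts$traces, function(tr) {
    corr <- correctBleach(tr, baselineWindow = basal,
                          assumeZeroOffset = TRUE)
    attr(corr, "bleachParams")$num$tau
  })
  expect_equal(median(taus), ts$truth$kinetics$bleach_tau, tolerance = 0.05)
})

test_that("patch generator honors the step protocol and silent channels", {
  cfg <- synthConfig(seed = 2)
  ps <- makePatchSweeps(cfg, nPatches = 1, sweepsPerPotential = 2)
  rec <- ps$recordings[[1]]
  expect_setequal(unique(rec@testMV), c(-60, -80, -100, -120))
  expect_equal(rec@fsHz, 10000)
  expect_equal(rec@filterHz, 1000)
  expect_equal(length(rec@sweeps[[1]]), 2 * 10000)  # 2 s steps
  # zero-conductance channel yields pure noise: silent idealization
  null <- makePatchSweeps(cfg, channel = list(gamma_pS = 0),
                          protocol = list(hold_mV = 0, test_mV = -80,
                                          dur_s = 1, every_s = 5),
                          nPatches = 1, sweepsPerPotential = 3)
  ide <- idealizeRecording(null$recordings[[1]])
  expect_true(all(sapply(ide, function(s) "silent" %in% s@flags)))
})

test_that("empirical open fraction matches the gating model at -80 mV", {
  cfg <- synthConfig(seed = 8)
  ps <- makePatchSweeps(cfg, protocol = list(hold_mV = 0, test_mV = -80,
                                             dur_s = 2, every_s = 5),
                        nPatches = 1, sweepsPerPotential = 30)
  iUnit <- 35e-3 * (-80)
  # idealization-free Markov oracle: mean current / unitary current = Po
  frac <- mean(sapply(ps$recordings[[1]]@sweeps, mean)) / iUnit
  po <- unname(ps$truth$po_at_V["-80"])
  # binomial-style CI on the time-averaged open fraction over 60 s
  se <- sqrt(2 * po * (1 - po) * 0.01 / 60)
  expect_lt(abs(frac - po), 4 * se + 0.01)
})

test_that("gold fields record true offsets and honor degenerate cases", {
  cfg <- synthConfig(seed = 13)
  gf <- makeGoldField(cfg, nParticles = 200,
                      placement = list(offset_mean_nm = 0, offset_sd_nm = 0,
                                       frac_near_omm = 1, frac_nucleus = 0))
  fld <- signedDistance(gf$field)
  expect_lt(max(abs(signedDistances(fld))), 0.1)  # all on the contour
  bad <- cbind(c(0, 10, 10, 0), c(0, 10, 0, 10))  # bow-tie
  expect_error(makeGoldField(cfg, ommContour = bad), "invalid_contour")
})

test_that("fraction sheets invert the formulas they were built from", {
  cfg <- synthConfig(seed = 5)
  even <- makeFractionSheet(cfg, trueSplit = list(pct_mito = 50,
                                                  pct_outer_leaflet = 50),
                            factors = list(D1 = 1, D2 = 1,
                                           K_pl = 1, K_dm = 1))
  expect_equal(unname(even$sheet@I_blot["cyto"]),
               unname(even$sheet@I_blot["p_mito"]))
  s <- makeFractionSheet(cfg, trueSplit = list(pct_mito = 25,
                                               pct_outer_leaflet = 70),
                         factors = list(D1 = 2, D2 = 1, K_pl = 1, K_dm = 1))
  expect_equal(pctMito(s$sheet)$pct_p_mito, 25, tolerance = 1e-12)
  expect_equal(pctLeaflet(s$sheet)$pct_outer_leaflet, 70, tolerance = 1e-12)
  noisy <- makeFractionSheet(cfg, noiseCV = 0.05)
  expect_false(identical(noisy$sheet@I_blot, even$sheet@I_blot))
})

test_that("dose-response sets carry the generating Hill curve", {
  cfg <- synthConfig(seed = 21)
  dr <- makeDoseResponseSet(cfg, EC50_uM = 2, cv = 0)
  fit <- fitHill(dr$data$conc_uM, dr$data$response, bootstrapB = 20)
  expect_equal(fit@fit$EC50_uM, 2, tolerance = 1e-6)
})
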