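# Single-channel analysis: idealization, NPo, occurrence, conductance, Po(V).

test_that("idealization conserves time exactly, silent sweeps included", {
  fs <- 10000
  flat <- rnorm(2 * fs, 0, 0.3)
  s <- idealize(flat, fs, 1000, polarity = "negative")
  expect_true("silent" %in% s@flags)
  expect_equal(s@openTimeS, 0)
  expect_identical(sum(s@dwells$duration_s), 2)
  cfg <- synthConfig(seed = 33)
  ps <- makePatchSweeps(cfg, nPatches = 1, sweepsPerPotential = 2)
  for (k in seq_along(ps$recordings[[1]]@sweeps)) {
    sw <- ps$recordings[[1]]@sweeps[[k]]
    ide <- idealize(sw, fs, 1000, polarity = "negative")
    expect_equal(sum(ide@dwells$duration_s), length(sw) / fs,
                 tolerance = 1e-12)
  }
})

test_that("noiseless square pulses are recovered with exact dwells", {
  fs <- 10000
  openRuns <- list(2001:4000, 8001:8500, 15001:17000)
  cur <- squarePulseSweep(2 * fs, openRuns, amp = -2.8)
  cur <- cur + rnorm(length(cur), 0, 1e-4)  # break histogram degeneracy
  s <- idealize(cur, fs, 1000, polarity = "negative")
  expect_equal(s@unitaryAmpPA, -2.8, tolerance = 1e-3)
  expect_equal(s@openTimeS, (2000 + 500 + 2000) / fs, tolerance = 2e-3)
  opens <- s@dwells[s@dwells$level == 1L, ]
  expect_equal(nrow(opens), 3)
  expect_equal(sort(opens$duration_s), c(0.05, 0.2, 0.2), tolerance = 0.01)
})

test_that("simulated channels at SNR ~6.7 recover open fraction within 10%", {
  cfg <- synthConfig(seed = 44)
  ps <- makePatchSweeps(cfg, protocol = list(hold_mV = 0, test_mV = -100,
                                             dur_s = 2, every_s = 5),
                        nPatches = 1, sweepsPerPotential = 15)
  ide <- idealizeRecording(ps$recordings[[1]])
  est <- npo(ide)
  truth <- unname(ps$truth$po_at_V["-100"])
  expect_equal(est, truth, tolerance = 0.10)
})

test_that("NPo covers the trivial and multi-channel cases", {
  mk <- function(levels, durs) {
    new("IdealizedSweep",
        dwells = data.frame(level = as.integer(levels), duration_s = durs),
        baselinePA = 0, unitaryAmpPA = -2.8,
        nLevels = max(as.integer(levels)),
        openTimeS = sum(levels * durs), fsHz = 1e4, flags = character())
  }
  expect_equal(npo(mk(0L, 2)), 0)          # always closed
  expect_equal(npo(mk(1L, 2)), 1)          # one channel always open
  expect_equal(npo(mk(c(0L, 2L), c(1, 1))), 1)  # level-weighted
  # two independent channels at Po 0.3 each: NPo ~ 0.6 over 60 s
  cfg <- synthConfig(seed = 3)
  ps <- makePatchSweeps(cfg,
                        protocol = list(hold_mV = 0, test_mV = -100,
                                        dur_s = 2, every_s = 5),
                        channel = list(gamma_pS = 35,
                                       po_at_V = function(V) 0.3, N = 2L),
                        nPatches = 1, sweepsPerPotential = 30)
  est <- npo(idealizeRecording(ps$recordings[[1]]))
  se <- sqrt(2 * 2 * 0.3 * 0.7 * 0.01 / 60)  # MC error over 60 s
  expect_lt(abs(est - 0.6), 4 * se + 0.02)
})

test_that("NPo estimation is unbiased on two-state simulations", {
  # 60 s simulated per seed through the full generate-filter-idealize path
  for (po in c(0.1, 0.5, 0.9)) {
    est <- sapply(1:20, function(s) {
      ps <- makePatchSweeps(synthConfig(seed = 500 + s),
                            protocol = list(hold_mV = 0, test_mV = -100,
                                            dur_s = 2, every_s = 5),
                            channel = list(gamma_pS = 35,
                                           po_at_V = function(V) po),
                            nPatches = 1, sweepsPerPotential = 30)
      npo(idealizeRecording(ps$recordings[[1]]))
    })
    expect_lt(abs(mean(est) - po), 0.02)
  }
})

test_that("mean current over unitary amplitude approximates NPo", {
  cfg <- synthConfig(seed = 55)
  ps <- makePatchSweeps(cfg, protocol = list(hold_mV = 0, test_mV = -80,
                                             dur_s = 2, every_s = 5),
                        nPatches = 1, sweepsPerPotential = 20)
  ide <- idealizeRecording(ps$recordings[[1]])
  iUnit <- mean(sapply(ide, function(s) s@unitaryAmpPA), na.rm = TRUE)
  oracle <- mean(sapply(ps$recordings[[1]]@sweeps, mean)) / iUnit
  expect_equal(npo(ide), oracle, tolerance = 0.05)
})

test_that("occurrence counts active patches, grouped by day", {
  mkSilent <- function() list(new("IdealizedSweep",
    dwells = data.frame(level = 0L, duration_s = 2), baselinePA = 0,
    unitaryAmpPA = NA_real_, nLevels = 0L, openTimeS = 0, fsHz = 1e4,
    flags = "silent"))
  mkActive <- function() list(new("IdealizedSweep",
    dwells = data.frame(level = c(0L, 1L), duration_s = c(1.5, 0.5)),
    baselinePA = 0, unitaryAmpPA = -2.8, nLevels = 1L, openTimeS = 0.5,
    fsHz = 1e4, flags = character()))
  expect_equal(occurrence(replicate(10, mkSilent(), simplify = FALSE))$
                 occurrence_pct, 0)
  mix <- c(replicate(7, mkActive(), simplify = FALSE),
           replicate(7, mkSilent(), simplify = FALSE))
  expect_equal(occurrence(mix)$occurrence_pct, 50)
  expect_error(occurrence(list()), "empty_set")
  # synthetic patch set with half the patches silent
  cfg <- synthConfig(seed = 66)
  ps <- makePatchSweeps(cfg, nPatches = 12, fracSilent = 0.5,
                        sweepsPerPotential = 1)
  occ <- occurrence(ps$recordings)
  expect_equal(occ$occurrence_pct, 100 * mean(!ps$truth$silent))
  expect_false(is.null(occ$per_day))
})

test_that("conductance equals the closed-form slope on exact lines", {
  iv <- data.frame(test_mV = c(-60, -80, -100, -120),
                   i_pA = 0.035 * c(-60, -80, -100, -120))
  g <- conductance(iv)
  expect_equal(g$gamma_pS, 35, tolerance = 1e-12)
  expect_error(conductance(data.frame(test_mV = c(-60, -80),
                                      i_pA = c(-2.1, -2.8))),
               "underdetermined")
  # silent recordings produce an empty i-V table and the same error
  cfg <- synthConfig(seed = 10)
  ps <- makePatchSweeps(cfg, channel = list(gamma_pS = 0), nPatches = 1,
                        sweepsPerPotential = 1)
  expect_error(conductance(ivTable(ps$recordings)), "underdetermined")
})

test_that("Po(V) increases with hyperpolarization as generated", {
  cfg <- synthConfig(seed = 77)
  ps <- makePatchSweeps(cfg, nPatches = 1, sweepsPerPotential = 10)
  pv <- poVoltage(ps$recordings)
  expect_equal(attr(pv, "N"), 1)
  expect_true(attr(pv, "monotone_with_hyperpolarization"))
  ord <- order(abs(pv$test_mV))
  expect_true(all(diff(pv$Po[ord]) > 0))
  expect_equal(pv$NPo, unname(ps$truth$po_at_V[as.character(pv$test_mV)]),
               tolerance = 0.25)
  # a calcium-free-like silent patch set stays silent at every potential
  silentSet <- makePatchSweeps(cfg, channel = list(gamma_pS = 0),
                               nPatches = 1, sweepsPerPotential = 2)
  pv0 <- poVoltage(silentSet$recordings)
  expect_equal(attr(pv0, "N"), 0)
  expect_true(all(is.na(pv0$Po)))
  expect_true(all(pv0$NPo == 0))
})
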