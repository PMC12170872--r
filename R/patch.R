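# Single-channel analysis of mitochondria-attached recordings: half-amplitude
# idealization with hysteresis, NPo, channel occurrence, slope conductance
# and Po(V).

# Minimum resolvable event duration: 1.8x the 10-90% rise time of the
# recording filter (Tr ~= 0.3321 / f_c for a Gaussian-like low-pass).
minDwellSamples <- function(fsHz, filterHz) {
  max(2L, ceiling(1.8 * 0.3321 / filterHz * fsHz))
}

# Noise SD from first differences (transitions are rare, so differencing
# removes the open/closed bimodality); conductance-level modes from the
# all-points density, keeping only peaks at least 3 sigma away from any
# larger accepted peak. The baseline (closed) level is the mode on the
# closed side: the most positive accepted mode when openings are inward.
currentModes <- function(cur, noiseSD) {
  # bandwidth floored at the density-grid resolution so near-noiseless
  # recordings still yield resolvable modes
  bw <- max(noiseSD / 2, diff(range(cur)) / 500, 1e-9)
  dens <- density(cur, n = 1024, bw = bw)
  isPeak <- which(c(FALSE, diff(sign(diff(dens$y))) < 0, FALSE))
  isPeak <- isPeak[dens$y[isPeak] > 0.01 * max(dens$y)]
  ord <- isPeak[order(dens$y[isPeak], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(dens$x[i] - dens$x[keep]) > 3 * noiseSD))
      keep <- c(keep, i)
  }
  keep <- keep[order(dens$x[keep])]
  list(x = dens$x[keep], y = dens$y[keep])
}

estimateBaselineNoise <- function(cur,
                                  polarity = c("auto", "negative",
                                               "positive"),
                                  lag = 1L) {
  polarity <- match.arg(polarity)
  # difference at a lag beyond the filter correlation time: adjacent samples
  # of low-pass-filtered noise are correlated and would understate sigma
  noiseSD <- max(mad(diff(cur, lag = lag)) / sqrt(2), 1e-6)
  modes <- currentModes(cur, noiseSD)
  baseline <- if (!length(modes$x)) median(cur) else switch(polarity,
    negative = max(modes$x), positive = min(modes$x),
    auto = modes$x[which.max(modes$y)])
  inb <- abs(cur - baseline) < 2.5 * noiseSD
  if (sum(inb) > 10) baseline <- mean(cur[inb])
  list(baseline = baseline, noiseSD = noiseSD, modes = modes)
}

findUnitaryAmp <- function(cur, baseline, noiseSD, minDwell,
                           polarity = c("auto", "negative", "positive"),
                           modes = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(modes)) modes <- currentModes(cur, noiseSD)
  sel <- abs(modes$x - baseline) > 3.5 * noiseSD
  if (polarity == "negative") sel <- sel & modes$x < baseline
  if (polarity == "positive") sel <- sel & modes$x > baseline
  cx <- modes$x[sel]; cy <- modes$y[sel]
  if (length(cx)) {
    # the unitary level is the open mode nearest the baseline, ignoring
    # minor density bumps from filter-smeared transition ramps
    cx <- cx[cy >= 0.25 * max(cy)]
    amp <- cx[which.min(abs(cx - baseline))] - baseline
    return(amp)
  }
  # fallback: sustained excursions beyond 4 sigma
  dev <- cur - baseline
  if (polarity == "negative") dev <- -dev
  if (polarity == "positive") dev <- dev
  if (polarity == "auto") dev <- abs(dev)
  open <- dev > 4 * noiseSD
  r <- rle(open)
  if (!any(r$values & r$lengths >= minDwell)) return(NULL)
  keep <- inverse.rle(structure(list(
    lengths = r$lengths, values = r$values & r$lengths >= minDwell),
    class = "rle"))
  med <- median(cur[keep]) - baseline
  if (abs(med) < 3 * noiseSD) NULL else med
}

#' Idealize a single-channel sweep
#'
#' Baseline and unitary amplitude come from the all-points histogram
#' (dominant mode = closed level; nearest substantial secondary mode = open
#' level). Transitions are detected at half-amplitude crossings with a
#' +/- 10 percent hysteresis band, and events shorter than 1.8x the filter
#' rise time are merged into their neighbours. A sweep with no secondary
#' mode and no sustained crossings idealizes as silent (valid, zero open
#' time).
#'
#' @param sweep numeric current vector (pA).
#' @param fsHz sampling rate (Hz).
#' @param filterHz recording filter corner (Hz).
#' @param polarity expected open-level polarity relative to baseline:
#'   "negative" for inward current at hyperpolarized potentials, "auto" to
#'   search both sides.
#' @return an \linkS4class{IdealizedSweep}; dwell durations always sum to
#'   the sweep duration.
#' @export
idealize <- function(sweep, fsHz, filterHz = 1000,
                     polarity = c("auto", "negative", "positive")) {
  polarity <- match.arg(polarity)
  n <- length(sweep)
  bn <- estimateBaselineNoise(sweep, polarity,
                              lag = max(1L, round(fsHz / filterHz)))
  minDwell <- minDwellSamples(fsHz, filterHz)
  amp <- findUnitaryAmp(sweep, bn$baseline, bn$noiseSD, minDwell, polarity,
                        modes = bn$modes)
  silentSweep <- function() {
    new("IdealizedSweep",
        dwells = data.frame(level = 0L, duration_s = n / fsHz),
        baselinePA = bn$baseline, unitaryAmpPA = NA_real_, nLevels = 0L,
        openTimeS = 0, fsHz = fsHz, flags = "silent")
  }
  if (is.null(amp)) return(silentSweep())
  u <- (sweep - bn$baseline) / amp
  lv <- integer(n)
  L <- 0L
  for (i in seq_len(n)) {
    ui <- u[i]
    while (ui > L + 0.6) L <- L + 1L
    while (ui < L - 0.6 && L > 0L) L <- L - 1L
    lv[i] <- L
  }
  # merge events shorter than the resolution limit into their neighbours
  repeat {
    r <- rle(lv)
    short <- which(r$lengths < minDwell)
    short <- short[short > 1L]
    if (!length(short)) break
    r$values[short[1]] <- r$values[short[1] - 1L]
    lv <- inverse.rle(r)
  }
  if (max(lv) == 0L) return(silentSweep())
  # refine the amplitude away from filter-smeared transition edges
  guard <- minDwell
  edges <- which(diff(lv) != 0)
  nearEdge <- rep(FALSE, n)
  for (e in edges)
    nearEdge[max(1, e - guard):min(n, e + guard)] <- TRUE
  c0 <- sweep[lv == 0L & !nearEdge]
  c1 <- sweep[lv == 1L & !nearEdge]
  ampOut <- if (length(c0) > 10 && length(c1) > 10)
    mean(c1) - mean(c0) else amp
  r <- rle(lv)
  dwells <- data.frame(level = as.integer(r$values),
                       duration_s = r$lengths / fsHz)
  new("IdealizedSweep", dwells = dwells, baselinePA = bn$baseline,
      unitaryAmpPA = ampOut, nLevels = max(lv),
      openTimeS = sum(dwells$level * dwells$duration_s),
      fsHz = fsHz, flags = character())
}

#' Idealize every sweep of a recording
#'
#' @param rec a \linkS4class{SingleChannelRecording}.
#' @param polarity per-sweep polarity; "from_voltage" (default) expects
#'   inward (negative) openings at negative test potentials.
#' @return list of \linkS4class{IdealizedSweep}, one per sweep.
#' @export
idealizeRecording <- function(rec, polarity = "from_voltage") {
  lapply(seq_along(rec@sweeps), function(k) {
    pol <- if (identical(polarity, "from_voltage")) {
      if (rec@testMV[k] < 0) "negative"
      else if (rec@testMV[k] > 0) "positive" else "auto"
    } else polarity
    idealize(rec@sweeps[[k]], rec@fsHz, rec@filterHz, polarity = pol)
  })
}

#' NPo from idealized sweeps at one potential
#'
#' NPo = sum over levels of level x (time at level) / total time, multi-level
#' aware.
#'
#' @param idealized list of \linkS4class{IdealizedSweep} (or a single one).
#' @return NPo (>= 0).
#' @export
npo <- function(idealized) {
  if (is(idealized, "IdealizedSweep")) idealized <- list(idealized)
  if (!length(idealized)) stop("need at least one sweep")
  tot <- sum(vapply(idealized, function(s) sum(s@dwells$duration_s),
                    numeric(1)))
  open <- sum(vapply(idealized, function(s) s@openTimeS, numeric(1)))
  open / tot
}

#' Channel occurrence across a patch set
#'
#' A patch is active if at least one resolved opening occurs at any test
#' potential; occurrence is the percentage of active patches, grouped per
#' experimental day when day labels exist.
#'
#' @param recordings list of \linkS4class{SingleChannelRecording} (one per
#'   patch), or a list of pre-computed idealization lists.
#' @return list: occurrence_pct (overall), active (logical per patch),
#'   per_day (data.frame or NULL).
#' @export
occurrence <- function(recordings) {
  if (!length(recordings)) mqStop("empty_set", "zero patches")
  active <- vapply(recordings, function(rec) {
    ide <- if (is(rec, "SingleChannelRecording")) idealizeRecording(rec)
           else rec
    any(vapply(ide, function(s) s@openTimeS > 0, logical(1)))
  }, logical(1))
  days <- vapply(recordings, function(rec)
    if (is(rec, "SingleChannelRecording")) rec@day else NA_character_,
    character(1))
  perDay <- NULL
  if (!all(is.na(days))) {
    perDay <- do.call(rbind, lapply(split(active, days), function(a)
      data.frame(n = length(a), active = sum(a),
                 occurrence_pct = 100 * mean(a))))
    perDay$day <- rownames(perDay)
  }
  list(occurrence_pct = 100 * mean(active), active = active,
       per_day = perDay)
}

#' Unitary current-voltage table from idealized recordings
#'
#' @param recordings list of \linkS4class{SingleChannelRecording}.
#' @param idealized optional pre-computed idealizations (same shape).
#' @return data.frame: test_mV, i_pA (mean unitary amplitude), n_sweeps.
#' @export
ivTable <- function(recordings, idealized = NULL) {
  if (is.null(idealized))
    idealized <- lapply(recordings, idealizeRecording)
  rows <- list()
  for (p in seq_along(recordings)) {
    rec <- recordings[[p]]
    for (k in seq_along(rec@sweeps)) {
      s <- idealized[[p]][[k]]
      if (!is.na(s@unitaryAmpPA) && s@openTimeS > 0)
        rows[[length(rows) + 1L]] <-
          data.frame(test_mV = rec@testMV[k], i_pA = s@unitaryAmpPA)
    }
  }
  if (!length(rows))
    return(data.frame(test_mV = numeric(), i_pA = numeric(),
                      n_sweeps = integer()))
  all <- do.call(rbind, rows)
  agg <- aggregate(i_pA ~ test_mV, all, mean)
  agg$n_sweeps <- aggregate(i_pA ~ test_mV, all, length)$i_pA
  attr(agg, "per_sweep") <- all
  agg
}

#' Slope conductance from an i-V table
#'
#' Least-squares slope of the unitary current vs test potential, in pS
#' (1 pA/mV = 1 nS = 1000 pS). A bootstrap CI over sweeps is attached when
#' per-sweep amplitudes are available.
#'
#' @param iv data.frame with test_mV and i_pA (from \code{\link{ivTable}}),
#'   needing >= 3 potentials.
#' @param bootstrapB bootstrap replicates for the CI (over sweeps).
#' @param seed bootstrap seed.
#' @return list: gamma_pS, ci95 (or NA), fit (lm), n_potentials.
#' @export
conductance <- function(iv, bootstrapB = 500L, seed = 1L) {
  if (nrow(iv) < 3 || length(unique(iv$test_mV)) < 3)
    mqStop("underdetermined", "need unitary amplitudes at >= 3 potentials")
  fit <- lm(i_pA ~ test_mV, iv)
  gamma <- unname(coef(fit)["test_mV"]) * 1000
  perSweep <- attr(iv, "per_sweep")
  ci <- c(NA_real_, NA_real_)
  if (!is.null(perSweep) && nrow(perSweep) >= 6) {
    groups <- split(seq_len(nrow(perSweep)), perSweep$test_mV)
    boots <- withSeed(as.integer(seed), {
      vapply(seq_len(bootstrapB), function(b) {
        idx <- unlist(lapply(groups, function(g)
          g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
        bs <- perSweep[idx, ]
        ag <- aggregate(i_pA ~ test_mV, bs, mean)
        if (nrow(ag) < 3) return(NA_real_)
        unname(coef(lm(i_pA ~ test_mV, ag))["test_mV"]) * 1000
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  list(gamma_pS = gamma, ci95 = ci, fit = fit,
       n_potentials = length(unique(iv$test_mV)))
}

#' Po as a function of voltage
#'
#' Po = NPo / N per test potential, with N the maximum number of
#' simultaneously open levels observed anywhere in the recordings (the
#' only estimate available without independent channel counting). Reports
#' whether Po increases monotonically with hyperpolarization.
#'
#' @param recordings list of \linkS4class{SingleChannelRecording}.
#' @param idealized optional pre-computed idealizations.
#' @return data.frame test_mV, NPo, Po plus attributes \code{N} and
#'   \code{monotone_with_hyperpolarization}; all-silent recordings return N
#'   = 0 and Po = NA (reported as silent).
#' @export
poVoltage <- function(recordings, idealized = NULL) {
  if (is.null(idealized))
    idealized <- lapply(recordings, idealizeRecording)
  volts <- sort(unique(unlist(lapply(recordings, function(r) r@testMV))),
                decreasing = TRUE)
  N <- max(c(0L, unlist(lapply(idealized, function(il)
    vapply(il, function(s) s@nLevels, integer(1))))))
  rows <- lapply(volts, function(V) {
    sel <- list()
    for (p in seq_along(recordings)) {
      k <- which(recordings[[p]]@testMV == V)
      sel <- c(sel, idealized[[p]][k])
    }
    data.frame(test_mV = V, NPo = npo(sel),
               Po = if (N > 0) npo(sel) / N else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "N") <- N
  # volts sorted decreasing: hyperpolarization = going down the rows
  attr(out, "monotone_with_hyperpolarization") <-
    if (N > 0) all(diff(out$NPo) >= -1e-12) else NA
  out
}
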