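# Synthetic-data generators. Every generator returns both the dataset and a
# GroundTruth record of the generating parameters, so downstream recovery
# tests read only generated data plus the recorded truth.

groundTruth <- function(generator, ...) {
  structure(list(generator = generator, ...), class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth <%s> with fields: %s\n", x$generator,
              paste(setdiff(names(x), "generator"), collapse = ", ")))
  invisible(x)
}

## ---- shapes -----------------------------------------------------------

shapeMask <- function(dim, centre, shape, params) {
  x <- slice.index(array(0, dim), 1)
  y <- slice.index(array(0, dim), 2)
  z <- slice.index(array(0, dim), 3)
  switch(shape,
    ellipsoid = {
      ax <- params$axes  # semi-axes in voxels, length 3
      ((x - centre[1]) / ax[1])^2 + ((y - centre[2]) / ax[2])^2 +
        ((z - centre[3]) / ax[3])^2 <= 1
    },
    tube = {
      L <- params$length; r <- params$radius
      abs(x - centre[1]) <= L / 2 &
        sqrt((y - centre[2])^2 + (z - centre[3])^2) <= r
    },
    branched = {
      # Y-shaped: trunk along -x plus two arms at +/-45 deg in the xy plane
      L <- params$length; r <- params$radius
      px <- x - centre[1]; py <- y - centre[2]; pz <- z - centre[3]
      capsule <- function(dx, dy, len) {
        t <- pmin(len, pmax(0, px * dx + py * dy))
        sqrt((px - t * dx)^2 + (py - t * dy)^2 + pz^2) <= r
      }
      capsule(-1, 0, L / 2) |
        capsule(1 / sqrt(2), 1 / sqrt(2), L / 2) |
        capsule(1 / sqrt(2), -1 / sqrt(2), L / 2)
    },
    stop("unknown shape: ", shape))
}

#' Generate a synthetic 3D mitochondria stack
#'
#' Places \code{nObjects} non-overlapping objects (tubes, ellipsoids or
#' Y-branched tubes) in a float stack, adds optional internal cristae texture
#' and Gaussian noise, and records per-object ground-truth masks. With
#' \code{cristae = "central"} the internal texture concentrates toward the
#' object centroid, emulating centrally condensed cristae.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param nObjects number of objects (>= 1).
#' @param shape "tube", "ellipsoid" or "branched".
#' @param cristae "uniform", "central" or "none".
#' @param dim stack dimensions in voxels (x, y, z).
#' @param shapeParams list; for ellipsoids \code{axes} (semi-axes, voxels),
#'   for tubes/branched \code{length} and \code{radius} (voxels).
#' @param objectIntensity,backgroundIntensity,cristaeBoost intensity model.
#' @return list with \code{stack} (\linkS4class{ImageStack3D}) and
#'   \code{truth} (GroundTruth holding per-object masks and parameters).
#' @export
makeMitoStack <- function(config, nObjects = 3L,
                          shape = c("tube", "ellipsoid", "branched"),
                          cristae = c("uniform", "central", "none"),
                          dim = c(64L, 64L, 16L),
                          shapeParams = NULL,
                          objectIntensity = 0.5,
                          backgroundIntensity = 0.05,
                          cristaeBoost = 0.3) {
  shape <- match.arg(shape)
  cristae <- match.arg(cristae)
  stopifnot(nObjects >= 1)
  if (is.null(shapeParams))
    shapeParams <- switch(shape,
      ellipsoid = list(axes = c(10, 5, 5)),
      tube = list(length = 24, radius = 4),
      branched = list(length = 24, radius = 4))
  withSeed(substreamSeed(config@seed, "mito_stack"), {
    extent <- switch(shape,  # per-axis half-extents in voxels
      ellipsoid = shapeParams$axes,
      tube = c(shapeParams$length / 2, shapeParams$radius,
               shapeParams$radius),
      branched = c(shapeParams$length / 2 + shapeParams$radius,
                   shapeParams$length / (2 * sqrt(2)) + shapeParams$radius,
                   shapeParams$radius))
    if (any(dim / 2 <= extent + 2))
      mqStop("placement_failed", "stack too small to contain objects")
    occupied <- array(FALSE, dim)
    masks <- list(); centres <- list()
    for (i in seq_len(nObjects)) {
      placed <- FALSE
      for (try in 1:50) {
        centre <- sapply(seq_len(3), function(k) {
          margin <- extent[k] + 2
          runif(1, 1 + margin, dim[k] - margin)
        })
        m <- shapeMask(dim, centre, shape, shapeParams)
        if (!any(m & occupied) && any(m)) {
          occupied <- occupied | m
          masks[[i]] <- m; centres[[i]] <- centre
          placed <- TRUE
          break
        }
      }
      if (!placed) mqStop("placement_failed",
                          sprintf("could not place object %d without overlap", i))
    }
    img <- array(backgroundIntensity, dim)
    cristaeMasks <- vector("list", nObjects)
    for (i in seq_len(nObjects)) {
      m <- masks[[i]]
      img[m] <- objectIntensity
      if (cristae != "none") {
        idx <- which(m)
        co <- arrayInd(idx, dim)
        ctr <- colMeans(co)
        r <- sqrt(rowSums(sweep(co, 2, ctr)^2))
        rmax <- max(r, 1e-9)
        p <- if (cristae == "uniform") rep(0.3, length(idx))
             else 0.6 * (1 - r / rmax)^2
        sel <- runif(length(idx)) < p
        cm <- array(FALSE, dim); cm[idx[sel]] <- TRUE
        cristaeMasks[[i]] <- cm
        img[idx[sel]] <- objectIntensity + cristaeBoost
      }
    }
    if (config@gaussianSD > 0)
      img <- img + array(rnorm(length(img), 0, config@gaussianSD), dim)
    stack <- new("ImageStack3D", channels = list(mito = img),
                 voxelXYnm = config@voxelXYnm, voxelZnm = config@voxelZnm,
                 frameIntervalS = NA_real_)
    truth <- groundTruth("mito_stack",
      shape = shape, cristae = cristae, shapeParams = shapeParams,
      centres = centres, masks = masks, cristaeMasks = cristaeMasks,
      objectIntensity = objectIntensity,
      backgroundIntensity = backgroundIntensity, seed = config@seed)
    list(stack = stack, truth = truth)
  })
}

## ---- traces -----------------------------------------------------------

#' Generate synthetic dual-channel ratiometric traces
#'
#' Both emission channels share a multiplicative exponential photobleaching
#' factor (making the ratio bleach-insensitive while single channels still
#' require correction); the Ca2+ transient rides on the numerator channel so
#' the ratio carries it. Additive Gaussian noise is scaled to each channel's
#' baseline (\code{config@gaussianSD} is the relative SD, i.e. 0.05 = SNR 20).
#'
#' @param config a \code{\link{synthConfig}}.
#' @param kinetics list: \code{baseline} (basal ratio level), \code{bleach_tau}
#'   (s, \code{Inf} disables bleaching), \code{transient_amp} (fractional rise
#'   of the ratio), \code{t_on} (stimulus onset, s), \code{decay} (transient
#'   decay constant, s).
#' @param nCells number of cells/traces.
#' @param durationS total duration (s).
#' @param label sensor label attached to each trace.
#' @return list with \code{traces} (list of \linkS4class{RawTrace}) and
#'   \code{truth}.
#' @export
makeTraceSet <- function(config,
                         kinetics = list(baseline = 1, bleach_tau = 120,
                                         transient_amp = 0.5, t_on = 150,
                                         decay = 30),
                         nCells = 10L, durationS = 300,
                         label = "IMS") {
  stopifnot(kinetics$bleach_tau > 0, nCells >= 1)
  withSeed(substreamSeed(config@seed, "trace_set"), {
    t <- seq(0, durationS, by = config@frameIntervalS)
    bleach <- if (is.finite(kinetics$bleach_tau))
      exp(-t / kinetics$bleach_tau) else rep(1, length(t))
    # finite rise, exponential decay; shape normalized so transient_amp is
    # the true peak fractional amplitude
    rise <- if (is.null(kinetics$rise)) 15 else kinetics$rise
    s <- pmax(t - kinetics$t_on, 0)
    shape <- (1 - exp(-s / rise)) * exp(-s / kinetics$decay)
    peakShape <- max(shape, (1 - exp(-seq(0, 10 * kinetics$decay, by = 0.1) /
                                       rise)) *
                       exp(-seq(0, 10 * kinetics$decay, by = 0.1) /
                             kinetics$decay))
    transient <- if (kinetics$transient_amp == 0) rep(0, length(t))
                 else kinetics$transient_amp * shape / peakShape
    # the transient rides on whichever channel is the ratio numerator for
    # this sensor label, so the derived ratio rises by (1 + transient)
    gem <- label %in% c("IMS", "cristae", "cyto_gcamp")
    traces <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      rnumBase <- 100 * exp(rnorm(1, 0, 0.05))
      rdenBase <- rnumBase / kinetics$baseline
      rnum <- rnumBase * (1 + transient) * bleach +
        rnorm(length(t), 0, config@gaussianSD * rnumBase)
      rden <- rdenBase * bleach +
        rnorm(length(t), 0, config@gaussianSD * rdenBase)
      traces[[i]] <- if (gem) rawTrace(t, rden, rnum, label = label)
                     else rawTrace(t, rnum, rden, label = label)
    }
    truth <- groundTruth("trace_set", kinetics = kinetics, nCells = nCells,
                         frameIntervalS = config@frameIntervalS,
                         relNoiseSD = config@gaussianSD, seed = config@seed)
    list(traces = traces, truth = truth)
  })
}

#' Generate synthetic concentration-response data from a Hill curve
#'
#' Per-cell peak responses at each tested concentration, drawn from a
#' four-parameter Hill curve with multiplicative lognormal noise
#' (mean-preserving) at the given coefficient of variation.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param EC50_uM,hill_n,floor,ceiling generating Hill parameters.
#' @param concUM tested concentrations (uM).
#' @param nCells cells per concentration.
#' @param cv lognormal coefficient of variation (default 0.10).
#' @return list with \code{data} (data.frame conc_uM, response, cell) and
#'   \code{truth}.
#' @export
makeDoseResponseSet <- function(config, EC50_uM = 1.3, hill_n = 1.2,
                                floor = 0.2, ceiling = 1.0,
                                concUM = c(0.1, 0.3, 1, 3, 10, 30, 100),
                                nCells = 50L, cv = 0.10) {
  stopifnot(EC50_uM > 0, all(concUM > 0), nCells >= 1, cv >= 0)
  withSeed(substreamSeed(config@seed, "dose_response"), {
    cu <- rep(concUM, each = nCells)
    mu <- hillPredict(cu, floor, ceiling, log10(EC50_uM), hill_n)
    resp <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      mu * rlnorm(length(cu), -sdlog^2 / 2, sdlog)
    } else mu
    truth <- groundTruth("dose_response", EC50_uM = EC50_uM,
                         hill_n = hill_n, floor = floor, ceiling = ceiling,
                         cv = cv, nCells = nCells, seed = config@seed)
    list(data = data.frame(conc_uM = cu, response = resp,
                           cell = rep(seq_len(nCells), length(concUM))),
         truth = truth)
  })
}

## ---- patch clamp ------------------------------------------------------

# Default open probability vs voltage: monotone increase with
# hyperpolarization (Boltzmann), used by the sweep generator.
defaultPoV <- function(V) 0.6 * stats::plogis((-90 - V) / 15)

simulateTwoState <- function(n, dt, tauO, tauC) {
  # alternate exponential dwells; returns 0/1 open state per sample
  state <- integer(0)
  open <- runif(1) < tauO / (tauO + tauC)
  while (length(state) < n) {
    tau <- if (open) tauO else tauC
    len <- max(1L, round(rexp(1, 1 / tau) / dt))
    state <- c(state, rep(as.integer(open), min(len, n - length(state))))
    open <- !open
  }
  state
}

lowPassFilter <- function(x, fsHz, filterHz) {
  bf <- signal::butter(4, filterHz / (fsHz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Generate synthetic mitochondria-attached patch sweeps
#'
#' Two-state Markov gating per channel with unitary current
#' \eqn{i(V) = \gamma (V - V_{rev})}; voltage steps of \code{dur_s} seconds
#' from the holding potential are delivered to each test potential. Gaussian
#' noise (SD a fraction of the unitary amplitude) is added at the sampling
#' rate and the trace is then low-pass filtered, emulating analog filtering
#' before digitization. A fraction of patches contains no channel.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param protocol list: hold_mV, test_mV (vector), dur_s, every_s.
#' @param channel list: gamma_pS, po_at_V (function of voltage in mV), N
#'   (channels per active patch), reversal_mV, tau_open_s.
#' @param nPatches number of patches.
#' @param fracSilent fraction of patches with no channel.
#' @param sweepsPerPotential sweeps recorded at each test potential.
#' @param fsHz,filterHz sampling rate and low-pass corner (Hz).
#' @param noiseSdFrac noise SD as fraction of the unitary amplitude.
#' @return list with \code{recordings} (list of
#'   \linkS4class{SingleChannelRecording}) and \code{truth}.
#' @export
makePatchSweeps <- function(config,
                            protocol = list(hold_mV = 0,
                                            test_mV = seq(-60, -120, by = -20),
                                            dur_s = 2, every_s = 5),
                            channel = list(gamma_pS = 35,
                                           po_at_V = defaultPoV,
                                           N = 1L, reversal_mV = 0,
                                           tau_open_s = 0.01),
                            nPatches = 1L, fracSilent = 0,
                            sweepsPerPotential = 5L,
                            fsHz = 10000, filterHz = 1000,
                            noiseSdFrac = 0.15) {
  stopifnot(channel$gamma_pS >= 0, fsHz >= 10000)
  if (is.null(channel$po_at_V)) channel$po_at_V <- defaultPoV
  if (is.null(channel$tau_open_s)) channel$tau_open_s <- 0.01
  if (is.null(channel$N)) channel$N <- 1L
  if (is.null(channel$reversal_mV)) channel$reversal_mV <- 0
  withSeed(substreamSeed(config@seed, "patch_sweeps"), {
    n <- round(protocol$dur_s * fsHz)
    dt <- 1 / fsHz
    silent <- runif(nPatches) < fracSilent
    recordings <- vector("list", nPatches)
    poTruth <- sapply(protocol$test_mV, channel$po_at_V)
    for (p in seq_len(nPatches)) {
      sweeps <- list(); testMV <- numeric(0)
      for (V in protocol$test_mV) {
        iUnit <- channel$gamma_pS * 1e-3 * (V - channel$reversal_mV)
        noiseSD <- noiseSdFrac * max(abs(iUnit), 0.5)
        po <- min(max(channel$po_at_V(V), 0), 1)
        tauO <- channel$tau_open_s
        tauC <- if (po > 0 && po < 1) tauO * (1 - po) / po else Inf
        for (s in seq_len(sweepsPerPotential)) {
          if (silent[p] || channel$gamma_pS == 0 || po == 0) {
            nOpen <- integer(n)
          } else if (po == 1) {
            nOpen <- rep(channel$N, n)
          } else {
            nOpen <- integer(n)
            for (ch in seq_len(channel$N))
              nOpen <- nOpen + simulateTwoState(n, dt, tauO, tauC)
          }
          cur <- nOpen * iUnit + rnorm(n, 0, noiseSD)
          sweeps[[length(sweeps) + 1L]] <- lowPassFilter(cur, fsHz, filterHz)
          testMV <- c(testMV, V)
        }
      }
      recordings[[p]] <- new("SingleChannelRecording", sweeps = sweeps,
                             testMV = testMV, fsHz = fsHz,
                             filterHz = filterHz,
                             protocol = protocol,
                             day = sprintf("day%d", 1L + (p - 1L) %/% 8L))
    }
    truth <- groundTruth("patch_sweeps",
      gamma_pS = channel$gamma_pS, N = channel$N,
      reversal_mV = channel$reversal_mV, tau_open_s = channel$tau_open_s,
      po_at_V = setNames(poTruth, protocol$test_mV), silent = silent,
      noiseSdFrac = noiseSdFrac, seed = config@seed)
    list(recordings = recordings, truth = truth)
  })
}

## ---- immunogold -------------------------------------------------------

circleContour <- function(centre, radius, nVertices = 256L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

#' Generate a synthetic immunogold particle field
#'
#' A closed OMM contour (default: a circular mitochondrion) sits inside a
#' raster cell with nucleus and cytosol masks. Near-membrane particles are
#' placed at signed normal offsets drawn from a Gaussian (positive = matrix
#' side); the rest are scattered through cytosol and nucleus. True
#' compartments and offsets are recorded.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param ommContour closed polygon (nm); default circle r = 250 nm.
#' @param nParticles total particle count.
#' @param placement list: \code{offset_mean_nm}, \code{offset_sd_nm},
#'   \code{frac_near_omm}, \code{frac_nucleus}.
#' @param fieldNm raster field edge length (nm).
#' @return list with \code{field} (\linkS4class{GoldParticleField}) and
#'   \code{truth}.
#' @export
makeGoldField <- function(config, ommContour = NULL, nParticles = 200L,
                          placement = list(offset_mean_nm = 15,
                                           offset_sd_nm = 5,
                                           frac_near_omm = 0.5,
                                           frac_nucleus = 0.1),
                          fieldNm = 1200) {
  mitoCentre <- c(0.65, 0.62) * fieldNm
  mitoR <- 250
  if (is.null(ommContour))
    ommContour <- circleContour(mitoCentre, mitoR)
  if (polygonSelfIntersects(ommContour))
    mqStop("invalid_contour", "OMM contour self-intersects")
  withSeed(substreamSeed(config@seed, "gold_field"), {
    nucCentre <- c(0.25, 0.25) * fieldNm; nucR <- 0.18 * fieldNm
    npx <- max(64L, round(fieldNm / config@temPxNm / 4) * 4)
    pxNm <- fieldNm / npx
    gx <- (row(matrix(0, npx, npx)) - 0.5) * pxNm
    gy <- (col(matrix(0, npx, npx)) - 0.5) * pxNm
    mitoMask <- matrix(pointInPolygon(cbind(as.numeric(gx), as.numeric(gy)),
                                      ommContour), npx, npx)
    nucMask <- (gx - nucCentre[1])^2 + (gy - nucCentre[2])^2 <= nucR^2
    cytoMask <- !mitoMask & !nucMask
    nNear <- round(nParticles * placement$frac_near_omm)
    nNuc <- round(nParticles * placement$frac_nucleus)
    nFar <- nParticles - nNear - nNuc
    # near-OMM particles: pick a contour point, walk its inward normal
    vidx <- sample(nrow(ommContour), nNear, replace = TRUE)
    offs <- rnorm(nNear, placement$offset_mean_nm, placement$offset_sd_nm)
    ctr <- colMeans(ommContour)
    pNear <- t(vapply(seq_len(nNear), function(i) {
      v <- ommContour[vidx[i], ]
      inward <- (ctr - v) / sqrt(sum((ctr - v)^2))
      v + inward * offs[i]
    }, numeric(2)))
    sampleInMask <- function(nwant, mask) {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < nwant) {
        cand <- cbind(runif(4 * nwant, 0, fieldNm),
                      runif(4 * nwant, 0, fieldNm))
        px <- pmin(npx, pmax(1L, ceiling(cand[, 1] / pxNm)))
        py <- pmin(npx, pmax(1L, ceiling(cand[, 2] / pxNm)))
        ok <- mask[cbind(px, py)]
        out <- rbind(out, cand[ok, , drop = FALSE])
      }
      out[seq_len(nwant), , drop = FALSE]
    }
    farFromOMM <- function(pts) {
      pointPolygonDistance(pts, ommContour) > 60
    }
    pFar <- sampleInMask(3 * nFar, cytoMask)
    pFar <- pFar[farFromOMM(pFar), , drop = FALSE]
    while (nrow(pFar) < nFar) {
      more <- sampleInMask(2 * nFar, cytoMask)
      pFar <- rbind(pFar, more[farFromOMM(more), , drop = FALSE])
    }
    pFar <- pFar[seq_len(nFar), , drop = FALSE]
    pNuc <- if (nNuc > 0) sampleInMask(nNuc, nucMask) else
      matrix(NA_real_, 0, 2)
    pts <- rbind(pNear, pFar, pNuc)
    trueComp <- c(rep("near_omm", nNear), rep("cytosol", nFar),
                  rep("nucleus", nNuc))
    field <- new("GoldParticleField", particles = pts,
                 contours = list(ommContour),
                 masks = list(mitochondria = mitoMask, nucleus = nucMask,
                              cytosol = cytoMask),
                 pxNm = pxNm)
    truth <- groundTruth("gold_field",
      offsets_nm = c(offs, rep(NA_real_, nFar + nNuc)),
      compartment = trueComp, mitoRadiusNm = mitoR,
      mitoCentreNm = mitoCentre, placement = placement, seed = config@seed)
    list(field = field, truth = truth)
  })
}

## ---- fractionation ----------------------------------------------------

#' Generate a synthetic fractionation band-intensity sheet
#'
#' Band intensities are constructed by algebraic inversion so that the
#' fractionation formulas applied to them return \code{trueSplit} exactly in
#' noiseless mode (or within the stated CV in noisy mode).
#'
#' @param config a \code{\link{synthConfig}}.
#' @param trueSplit list: \code{pct_mito} (percent of AnxA5 in pure
#'   mitochondria vs cytosol) and \code{pct_outer_leaflet} (percent digested
#'   by proteinase K, i.e. on the cytosolic leaflet).
#' @param factors list: \code{D1}, \code{D2} (named per-lane dilution and
#'   process-compensation factors or scalars), \code{K_pl}, \code{K_dm}.
#' @param noiseCV lognormal coefficient of variation on intensities (0 =
#'   noiseless).
#' @return list with \code{sheet} (\linkS4class{FractionSheet}) and
#'   \code{truth}.
#' @export
makeFractionSheet <- function(config,
                              trueSplit = list(pct_mito = 30,
                                               pct_outer_leaflet = 70),
                              factors = list(D1 = 1, D2 = 1,
                                             K_pl = 1, K_dm = 1),
                              noiseCV = 0) {
  stopifnot(trueSplit$pct_mito > 0, trueSplit$pct_mito <= 100,
            trueSplit$pct_outer_leaflet > 0,
            trueSplit$pct_outer_leaflet <= 100)
  lanes <- c("cyto", "p_mito", "p_mito_PK")
  expand <- function(x) if (length(x) == 1) setNames(rep(x, 3), lanes)
    else x[lanes]
  D1 <- expand(factors$D1); D2 <- expand(factors$D2)
  stopifnot(all(D1 > 0), all(D2 > 0), factors$K_pl > 0, factors$K_dm > 0)
  aMito <- 1
  aCyto <- aMito * (100 * factors$K_pl / trueSplit$pct_mito - 1)
  aPK <- aMito * (100 * factors$K_dm / trueSplit$pct_outer_leaflet - 1)
  if (aCyto < 0 || aPK < 0)
    stop("trueSplit is not reachable with the given K factors")
  amounts <- c(cyto = aCyto, p_mito = aMito, p_mito_PK = aPK)
  I <- amounts / (D1 * D2)
  withSeed(substreamSeed(config@seed, "fraction_sheet"), {
    if (noiseCV > 0) {
      sdlog <- sqrt(log(1 + noiseCV^2))
      I <- I * rlnorm(3, -sdlog^2 / 2, sdlog)
    }
    sheet <- fractionSheet(I_blot = I, D1 = D1, D2 = D2,
                           K_pl = factors$K_pl, K_dm = factors$K_dm)
    truth <- groundTruth("fraction_sheet", trueSplit = trueSplit,
                         factors = factors, noiseCV = noiseCV,
                         seed = config@seed)
    list(sheet = sheet, truth = truth)
  })
}
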