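# Ratiometric trace processing: background subtraction, photobleaching
# correction by exponential extrapolation of the basal phase, ratio and
# response metrics, TMRM membrane-potential ratio, and Hill EC50 fitting.

#' Subtract background from both channels of a raw trace
#'
#' Background may be a scalar or a vector of trace length per channel.
#' Negative corrected values are permitted and flagged.
#'
#' @param raw a \linkS4class{RawTrace}.
#' @return the trace with backgrounds subtracted and zeroed.
#' @export
subtractBackground <- function(raw) {
  n <- length(raw@timeS)
  for (bg in list(raw@bgNum, raw@bgDen)) {
    if (!length(bg) %in% c(1L, n))
      mqStop("length_mismatch", "background longer than trace")
    if (any(!is.finite(bg))) mqStop("length_mismatch", "background not finite")
  }
  chNum <- raw@chNum - raw@bgNum
  chDen <- raw@chDen - raw@bgDen
  flags <- raw@flags
  if (any(chNum < 0) || any(chDen < 0))
    flags <- union(flags, "negative_after_bg")
  if (all(abs(chNum) < .Machine$double.eps * 100) ||
      all(abs(chDen) < .Machine$double.eps * 100)) {
    warning("a channel is identically zero after background subtraction")
    flags <- union(flags, "zero_channel")
  }
  initialize(raw, chNum = chNum, chDen = chDen, bgNum = 0, bgDen = 0,
             flags = flags)
}

fitExpDecay <- function(t, y, fixC = FALSE) {
  # y = A exp(-t/tau) + C fitted on the basal phase (Levenberg-Marquardt);
  # fixC pins the offset at zero for background-free intensities
  C0 <- if (fixC) 0 else max(min(y), 0)
  A0 <- max(y[1] - C0, 1e-6 * max(abs(y), 1))
  tau0 <- max(diff(range(t)), 1e-6)
  resid <- function(p) {
    C <- if (fixC) 0 else p[3]
    y - (p[1] * exp(-t / p[2]) + C)
  }
  par0 <- if (fixC) c(A0, tau0) else c(A0, tau0, C0)
  lower <- if (fixC) c(0, 1e-9) else c(0, 1e-9, 0)  # non-negative intensities
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info %in% c(0, 9)) return(NULL)
  p <- fit$par
  list(A = p[1], tau = p[2], C = if (fixC) 0 else p[3])
}

#' Correct photobleaching by exponential extrapolation of the basal phase
#'
#' Fits \eqn{y = A e^{-t/\tau} + C} to each channel inside the baseline
#' window and divides the full trace by the extrapolated curve normalized to
#' its value at the first sample, so the corrected baseline is flat. If the
#' exponential fit does not converge, a linear fit is used instead and the
#' trace is flagged \code{"bleach_linear_fallback"}.
#'
#' @param raw a \linkS4class{RawTrace}, background-subtracted.
#' @param baselineWindow integer index vector of basal-phase samples
#'   (>= 10 samples, before stimulation). Default: first 60 s.
#' @param assumeZeroOffset pin the fitted offset C at zero, appropriate for
#'   background-subtracted intensities whose bleaching is purely
#'   multiplicative.
#' @return corrected \linkS4class{RawTrace} with an attribute-style record of
#'   the per-channel fit in \code{flags}/\code{bleachParams} (see
#'   \code{attr(x, "bleachParams")}).
#' @export
correctBleach <- function(raw, baselineWindow = NULL,
                          assumeZeroOffset = FALSE) {
  t <- raw@timeS
  if (is.null(baselineWindow))
    baselineWindow <- which(t <= t[1] + 60)
  baselineWindow <- as.integer(baselineWindow)
  if (length(baselineWindow) < 10)
    stop("baseline window must contain at least 10 samples")
  flags <- raw@flags
  params <- list()
  channels <- list(num = raw@chNum, den = raw@chDen)
  for (nm in names(channels)) {
    y <- channels[[nm]]
    fit <- fitExpDecay(t[baselineWindow], y[baselineWindow],
                       fixC = assumeZeroOffset)
    if (is.null(fit)) {
      lf <- lm(y[baselineWindow] ~ t[baselineWindow])
      pred <- coef(lf)[1] + coef(lf)[2] * t
      flags <- union(flags, "bleach_linear_fallback")
      params[[nm]] <- list(A = NA_real_, tau = NA_real_, C = NA_real_,
                           linear = as.numeric(coef(lf)))
    } else {
      pred <- fit$A * exp(-t / fit$tau) + fit$C
      params[[nm]] <- fit
    }
    norm <- pred / pred[1]
    norm[norm <= 0 | !is.finite(norm)] <- NA_real_
    channels[[nm]] <- y / norm
  }
  out <- initialize(raw, chNum = channels$num, chDen = channels$den,
                    flags = flags)
  attr(out, "bleachParams") <- params
  out
}

# which labels put the 480 nm emission in the numerator: GEM-GECO sensors
# have the Ca-bound species emitting at the shorter wavelength.
gemLabels <- c("IMS", "cristae", "cyto_gcamp")

#' Compute the ratio trace and response metrics
#'
#' The numerator convention is label-specific so a Ca2+ rise is positive for
#' every sensor: FRET sensors (matrix 4mtD3cpv, ER D1ER, MICU1-FRET) use
#' 530/480, GEM-GECO sensors use 480/530, Fura-2 uses 340/385. Samples with a
#' non-positive denominator are masked; more than 10 percent masked raises
#' \code{ratio_unreliable}.
#'
#' @param raw a processed \linkS4class{RawTrace}.
#' @param baselineWindow index vector for the basal value (default first 60 s).
#' @param direction "up" for rises (delta = peak - basal) or "down" for
#'   depletion responses (delta = basal - nadir).
#' @param numerator optional override: "chNum" or "chDen".
#' @return a \linkS4class{RatioTrace}.
#' @export
computeRatio <- function(raw, baselineWindow = NULL,
                         direction = c("up", "down"), numerator = NULL) {
  direction <- match.arg(direction)
  t <- raw@timeS
  if (is.null(baselineWindow)) baselineWindow <- which(t <= t[1] + 60)
  baselineWindow <- as.integer(baselineWindow)
  if (is.null(numerator))
    numerator <- if (raw@label %in% gemLabels) "chDen" else "chNum"
  num <- slot(raw, numerator)
  den <- slot(raw, setdiff(c("chNum", "chDen"), numerator))
  masked <- !is.finite(den) | den <= 0 | !is.finite(num)
  ratio <- ifelse(masked, NA_real_, num / den)
  flags <- raw@flags
  if (any(masked)) flags <- union(flags, "masked_samples")
  if (mean(masked) > 0.1) mqStop("ratio_unreliable",
                                 sprintf("%.0f%% of samples masked",
                                         100 * mean(masked)))
  basal <- mean(ratio[baselineWindow], na.rm = TRUE)
  sm <- movingAverage(ifelse(is.na(ratio), basal, ratio), 5L)
  post <- setdiff(seq_along(ratio), baselineWindow)
  if (!length(post)) post <- seq_along(ratio)
  if (direction == "up") {
    peak <- max(sm[post]); delta <- max(peak - basal, 0)
  } else {
    peak <- min(sm[post]); delta <- max(basal - peak, 0)
  }
  bp <- attr(raw, "bleachParams")
  new("RatioTrace", timeS = t, ratio = ratio, masked = masked,
      basal = basal, peak = peak, delta = delta, direction = direction,
      bleachParams = if (is.null(bp)) list() else bp,
      baselineWindow = baselineWindow, flags = flags)
}

#' Mitochondria-to-nucleus TMRM ratio
#'
#' Per-frame ratio of mean background-subtracted mitochondrial intensity to
#' mean nuclear intensity; the basal membrane-potential readout is the mean
#' ratio before the depolarization marker, the FCCP endpoint the mean after.
#'
#' @param frames 3D array (x, y, frame) or a list of matrices.
#' @param mitoMask,nucleusMask disjoint logical masks.
#' @param fccpFrame optional first frame index after full depolarization.
#' @return list: \code{ratio} (per frame), \code{basal}, \code{fccp}.
#' @export
tmrmPotential <- function(frames, mitoMask, nucleusMask, fccpFrame = NULL) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2) dim(frames) <- c(dim(frames), 1L)
  if (!any(mitoMask) || !any(nucleusMask))
    mqStop("empty_roi", "mito and nucleus masks must be non-empty")
  if (any(mitoMask & nucleusMask))
    stop("mito and nucleus masks must be disjoint")
  nf <- dim(frames)[3]
  ratio <- vapply(seq_len(nf), function(k) {
    fr <- frames[, , k]
    mean(fr[mitoMask]) / mean(fr[nucleusMask])
  }, numeric(1))
  basalIdx <- if (is.null(fccpFrame)) seq_len(nf) else seq_len(fccpFrame - 1L)
  fccp <- if (is.null(fccpFrame)) NA_real_ else mean(ratio[fccpFrame:nf])
  list(ratio = ratio, basal = mean(ratio[basalIdx]), fccp = fccp)
}

hillPredict <- function(conc, floor, ceiling, logEC50, hill) {
  floor + (ceiling - floor) / (1 + 10^((logEC50 - log10(conc)) * hill))
}

#' Fit a four-parameter Hill (log-logistic) concentration-response curve
#'
#' Fits \eqn{r(c) = floor + (ceiling - floor) / (1 + 10^{(\log_{10}EC_{50} -
#' \log_{10}c)\,h})} on log10 concentration with a bootstrap 95 percent CI
#' for the EC50 (case resampling within concentration groups, seeded).
#'
#' @param concUM concentration per observation (uM), >= 4 distinct values.
#' @param response response per observation.
#' @param bootstrapB bootstrap replicates (default 1000).
#' @param seed bootstrap seed (recorded in the result).
#' @return a \linkS4class{DoseResponse}.
#' @export
fitHill <- function(concUM, response, bootstrapB = 1000L, seed = 1L) {
  stopifnot(length(concUM) == length(response), all(concUM > 0))
  if (length(unique(concUM)) < 4)
    stop("need at least 4 distinct concentrations")
  means <- tapply(response, concUM, mean)
  if (diff(range(means)) < 1e-9 * max(abs(means), 1))
    mqStop("degenerate_response", "flat response; floor equals ceiling")
  fit1 <- fitHillOnce(concUM, response)
  flags <- character()
  r2 <- fit1$r2
  if (is.finite(r2) && r2 < 0.5) flags <- c(flags, "poor_fit")
  span <- range(concUM)
  if (fit1$EC50_uM < span[1] || fit1$EC50_uM > span[2])
    flags <- c(flags, "extrapolated")
  groups <- split(seq_along(concUM), concUM)
  boots <- withSeed(as.integer(seed), {
    vapply(seq_len(bootstrapB), function(b) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
      bf <- try(fitHillOnce(concUM[idx], response[idx]), silent = TRUE)
      if (inherits(bf, "try-error") || is.null(bf)) NA_real_ else bf$EC50_uM
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  new("DoseResponse", concUM = concUM, response = response,
      fit = fit1, ci95 = ci, seed = as.integer(seed), flags = flags)
}

fitHillOnce <- function(concUM, response) {
  lc <- log10(concUM)
  means <- tapply(response, concUM, mean)
  lo <- min(means); hi <- max(means)
  increasing <- means[length(means)] >= means[1]
  half <- (lo + hi) / 2
  concs <- as.numeric(names(means))
  start <- list(floor = if (increasing) lo else hi,
                ceiling = if (increasing) hi else lo,
                logEC50 = lc[which.min(abs(means - half))[1]],
                hill = if (increasing) 1 else 1)
  names(start$logEC50) <- NULL
  fit <- try(minpack.lm::nlsLM(
    response ~ hillPredict(concUM, floor, ceiling, logEC50, hill),
    start = start,
    lower = c(-Inf, -Inf, min(lc) - 3, 0.05),
    upper = c(Inf, Inf, max(lc) + 3, 20),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- as.list(coef(fit))
  ss <- sum(resid(fit)^2)
  sst <- sum((response - mean(response))^2)
  list(EC50_uM = 10^cf$logEC50, hill_n = cf$hill, floor = cf$floor,
       ceiling = cf$ceiling, logEC50 = cf$logEC50,
       r2 = if (sst > 0) 1 - ss / sst else NA_real_)
}
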