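# Histogram-based automatic thresholds. All operate on a fixed-bin histogram
# of the input intensities and return a threshold on the intensity scale;
# pixels strictly above the threshold are foreground.

histogramBins <- function(x, nbins, range = NULL) {
  if (is.null(range)) range <- range(x, finite = TRUE)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5) * max(abs(range), 1)
  breaks <- seq(range[1], range[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(nbins, pmax(1L, findInterval(
    x, breaks, rightmost.closed = TRUE))), nbins)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  list(counts = counts, mids = mids, breaks = breaks)
}

# Otsu: maximise between-class variance over all histogram cuts.
# Constant input has no split: the value itself is returned, so a strict
# `> threshold` foreground test stays empty.
otsuThreshold <- function(x, nbins = 256L, range = NULL) {
  if (diff(range(x, finite = TRUE)) == 0) return(x[1])
  h <- histogramBins(as.numeric(x), nbins, range)
  p <- h$counts / sum(h$counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * h$mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins])
  h$breaks[k + 1L]
}

# Yen's maximum-correlation criterion.
yenThreshold <- function(x, nbins = 256L, range = NULL) {
  if (diff(range(x, finite = TRUE)) == 0) return(x[1])
  h <- histogramBins(as.numeric(x), nbins, range)
  p <- h$counts / sum(h$counts)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- -log(pmax(P1sq * P2sq, .Machine$double.xmin)) +
    2 * log(pmax(P1 * (1 - P1), .Machine$double.xmin))
  crit[!is.finite(crit)] <- -Inf
  k <- which.max(crit[-nbins])
  h$breaks[k + 1L]
}

# Kapur maximum-entropy ("MaxEntropy") threshold: maximise the sum of the
# Shannon entropies of the background and foreground histograms.
kapurThreshold <- function(x, nbins = 256L, range = NULL) {
  if (diff(range(x, finite = TRUE)) == 0) return(x[1])
  h <- histogramBins(as.numeric(x), nbins, range)
  p <- h$counts / sum(h$counts)
  P1 <- cumsum(p)
  ent <- function(q) ifelse(q > 0, -q * log(q), 0)
  H1 <- cumsum(ent(p))
  HT <- H1[nbins]
  crit <- rep(-Inf, nbins)
  ok <- P1 > 0 & P1 < 1
  crit[ok] <- log(P1[ok] * (1 - P1[ok])) + H1[ok] / P1[ok] +
    (HT - H1[ok]) / (1 - P1[ok])
  k <- which.max(crit[-nbins])
  h$breaks[k + 1L]
}

# Per-pixel local Otsu threshold within a circular window, computed with one
# box-sum pass per histogram bin (binned to `nbins` levels for tractability).
# Windows with less than `minContrast` of the reference (stack) dynamic range
# carry no foreground/background mixture worth splitting; their pixels defer
# to the global threshold instead of an arbitrary local cut.
localOtsuMask <- function(img, radiusPx, nbins = 64L, globalThr = NULL,
                          globalRange = NULL, minContrast = 0.5) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  if (is.null(globalRange)) globalRange <- diff(rng)
  if (is.null(globalThr)) globalThr <- otsuThreshold(img)
  h <- histogramBins(as.numeric(img), nbins, rng)
  binIdx <- matrix(pmin(nbins, pmax(1L, findInterval(
    img, h$breaks, rightmost.closed = TRUE))), nrow(img), ncol(img))
  brush <- EBImage::makeBrush(2 * radiusPx + 1, shape = "disc")
  npx <- length(img)
  counts <- matrix(0, npx, nbins)
  for (b in seq_len(nbins)) {
    ind <- (binIdx == b) * 1
    counts[, b] <- as.numeric(EBImage::filter2(ind, brush / 1,
                                               boundary = 0))
  }
  counts[counts < 0] <- 0
  U <- upper.tri(diag(nbins), diag = TRUE) * 1  # counts %*% U = cum counts
  W <- counts %*% U
  Mu <- sweep(counts, 2, h$mids, `*`) %*% U
  Wtot <- W[, nbins]; MuTot <- Mu[, nbins]
  sb <- (MuTot * W - Mu * Wtot)^2 / (W * (Wtot - W))
  sb[!is.finite(sb)] <- -Inf
  kbest <- max.col(sb[, -nbins, drop = FALSE], ties.method = "first")
  thr <- h$breaks[kbest + 1L]
  noVar <- apply(sb, 1, max) == -Inf
  nz <- counts > 0.5  # filter2 is FFT-based; suppress numerical residue
  lowIdx <- max.col(nz, ties.method = "first")
  highIdx <- nbins + 1L - max.col(nz[, nbins:1, drop = FALSE],
                                  ties.method = "first")
  binW <- diff(h$breaks[1:2])
  localRange <- (highIdx - lowIdx) * binW
  defer <- noVar | localRange < minContrast * globalRange
  out <- as.numeric(img) > thr
  out[defer] <- as.numeric(img)[defer] > globalThr
  matrix(out, nrow(img), ncol(img))
}
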