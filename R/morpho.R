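# 3D segmentation and morphometry of mitochondria, colocalization, contact
# site visualization, 2D SIM morphology, PLA dot counting and cluster sizing.

rollingBallBackground <- function(slice, radiusPx) {
  # grayscale opening with a disc approximates the rolling-ball background
  brush <- EBImage::makeBrush(2 * radiusPx + 1, shape = "disc")
  as.matrix(EBImage::opening(slice, brush))
}

#' Segment mitochondria in a 3D stack
#'
#' Pipeline: per-slice rolling-ball-style background subtraction (grayscale
#' opening with a disc), then the intersection of a global Otsu mask (stack
#' histogram) and a per-slice local Otsu mask (circular window, default
#' radius 640 nm), then 26-connected 3D labeling with small objects removed.
#' The global/local merge is a logical AND: the per-slice local threshold
#' marks spurious foreground in empty slices, which the global mask
#' suppresses.
#'
#' @param stack an \linkS4class{ImageStack3D} (single channel used).
#' @param channel channel name (default: first channel).
#' @param rollingBallRadiusPx background radius in pixels (default 50).
#' @param localRadiusNm local Otsu window radius in nm (default 640).
#' @param minObjectVoxels minimum object size in voxels (default 10).
#' @param useLocal set FALSE to skip the local mask (global Otsu only).
#' @return a \linkS4class{SegmentationResult}.
#' @export
segmentMito <- function(stack, channel = NULL, rollingBallRadiusPx = 50L,
                        localRadiusNm = 640, minObjectVoxels = 10L,
                        useLocal = TRUE) {
  if (is.null(channel)) channel <- channelNames(stack)[1]
  img <- getChannel(stack, channel)
  d <- dim(img)
  corrected <- img
  for (k in seq_len(d[3])) {
    bg <- rollingBallBackground(img[, , k], rollingBallRadiusPx)
    corrected[, , k] <- img[, , k] - bg
  }
  thrGlobal <- otsuThreshold(corrected)
  maskGlobal <- corrected > thrGlobal
  if (useLocal) {
    radiusPx <- max(1L, round(localRadiusNm / stack@voxelXYnm))
    gRange <- diff(range(corrected, finite = TRUE))
    maskLocal <- array(FALSE, d)
    for (k in seq_len(d[3]))
      maskLocal[, , k] <- localOtsuMask(corrected[, , k], radiusPx,
                                        globalThr = thrGlobal,
                                        globalRange = gRange)
    mask <- maskGlobal & maskLocal
  } else {
    mask <- maskGlobal
  }
  if (!any(mask)) mqStop("no_objects", "empty foreground after thresholding")
  labels <- label3D26(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= minObjectVoxels)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  if (!any(labels > 0)) mqStop("no_objects", "all objects below size cutoff")
  new("SegmentationResult", labels = labels, thresholdGlobal = thrGlobal,
      localRadiusNm = localRadiusNm,
      minObjectVoxels = as.integer(minObjectVoxels),
      voxelXYnm = stack@voxelXYnm, voxelZnm = stack@voxelZnm)
}

boundaryFaceArea <- function(mask, dxy, dz) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  exposed <- function(shifted) sum(core & !shifted)
  nx <- exposed(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]) +
    exposed(pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE])
  ny <- exposed(pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE]) +
    exposed(pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE])
  nz <- exposed(pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE]) +
    exposed(pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE])
  nx * dxy * dz + ny * dxy * dz + nz * dxy * dxy
}

#' Measure 3D morphology of segmented mitochondria
#'
#' Per object: volume (voxel count times voxel volume), surface (summed
#' boundary-face area, anisotropy-aware), ellipsoid semi-axes from the second
#' central moments of the voxel coordinates (semi-axis = sqrt(5 lambda), the
#' uniform-solid-ellipsoid convention), elongation a/b, flatness b/c, and the
#' branching index volume / ((4/3) pi a b c) — lower values indicate more
#' branched objects.
#'
#' @param seg a \linkS4class{SegmentationResult}.
#' @return data.frame with one row per object (um-based units); objects
#'   touching the stack border carry \code{truncated = TRUE}.
#' @export
measure3D <- function(seg) {
  labels <- seg@labels
  d <- dim(labels)
  nObj <- max(labels)
  if (nObj == 0) mqStop("no_objects", "no labeled objects")
  dxy <- seg@voxelXYnm / 1000; dz <- seg@voxelZnm / 1000  # um
  voxVol <- dxy * dxy * dz
  out <- lapply(seq_len(nObj), function(i) {
    idx <- which(labels == i)
    co <- arrayInd(idx, d)
    truncated <- any(co[, 1] %in% c(1L, d[1])) ||
      any(co[, 2] %in% c(1L, d[2])) || any(co[, 3] %in% c(1L, d[3]))
    phys <- cbind(co[, 1] * dxy, co[, 2] * dxy, co[, 3] * dz)
    vol <- length(idx) * voxVol
    mask <- array(FALSE, d); mask[idx] <- TRUE
    surf <- boundaryFaceArea(mask, dxy, dz)
    ctr <- colMeans(phys)
    cv <- crossprod(sweep(phys, 2, ctr)) / nrow(phys)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    semi <- sqrt(5 * pmax(ev, 1e-12))
    ellVol <- 4 / 3 * pi * prod(semi)
    data.frame(id = i, volume_um3 = vol, surface_um2 = surf,
               a_um = semi[1], b_um = semi[2], c_um = semi[3],
               elongation = semi[1] / semi[2], flatness = semi[2] / semi[3],
               branching = vol / ellVol, n_voxels = length(idx),
               truncated = truncated)
  })
  do.call(rbind, out)
}

#' Pearson colocalization coefficient within a cell mask
#'
#' @param ch1,ch2 arrays of identical geometry.
#' @param cellMask logical mask selecting the voxels to correlate.
#' @return Pearson r.
#' @export
pearsonColoc <- function(ch1, ch2, cellMask = NULL) {
  if (!identical(dim(ch1), dim(ch2))) stop("channels must share geometry")
  if (is.null(cellMask)) cellMask <- array(TRUE, dim(ch1))
  if (!any(cellMask)) mqStop("empty_roi", "cell mask is empty")
  x <- ch1[cellMask]; y <- ch2[cellMask]
  if (var(x) == 0 || var(y) == 0)
    mqStop("undefined_correlation", "zero variance in a channel")
  cor(x, y)
}

#' Pixelwise mitochondria-x-ER product image (contact-site visualization)
#'
#' @param mitoCh,erCh co-registered channels.
#' @param gain multiplicative gain applied to the product.
#' @param clipMax clip ceiling (default: no clipping).
#' @return array of the same geometry.
#' @export
mercsProductImage <- function(mitoCh, erCh, gain = 1, clipMax = Inf) {
  if (!identical(dim(mitoCh), dim(erCh))) stop("channels must share geometry")
  pmin(mitoCh * erCh * gain, clipMax)
}

moments2D <- function(coords) {
  ctr <- colMeans(coords)
  cv <- crossprod(sweep(coords, 2, ctr)) / nrow(coords)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  # semi-axis of the equivalent uniform ellipse: lambda = axis^2 / 4
  2 * sqrt(pmax(ev, 1e-12))
}

#' Binarize a 2D frame with the Yen auto threshold
#'
#' @param frame numeric matrix.
#' @return logical mask (pixels above the Yen threshold).
#' @export
yenBinarize <- function(frame) frame > yenThreshold(frame)

#' 2D morphology of binarized mitochondria (SIM mode)
#'
#' Per 8-connected object: area (um^2) and the major/minor axes from the 2D
#' second moments; aspect ratio = major/minor >= 1.
#'
#' @param binary logical matrix (e.g. from \code{\link{yenBinarize}}).
#' @param pxNm pixel size in nm.
#' @param minAreaPx discard objects smaller than this (pixels).
#' @return data.frame: id, area_um2, major_um, minor_um, aspect_ratio; the
#'   object count is \code{nrow()}.
#' @export
measure2D <- function(binary, pxNm, minAreaPx = 4L) {
  labels <- EBImage::bwlabel(binary * 1)
  n <- max(labels)
  rows <- list()
  for (i in seq_len(n)) {
    idx <- which(labels == i, arr.ind = TRUE)
    if (nrow(idx) < minAreaPx) next
    ax <- moments2D(idx) * pxNm / 1000
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L,
      area_um2 = nrow(idx) * (pxNm / 1000)^2,
      major_um = ax[1], minor_um = ax[2],
      aspect_ratio = ax[1] / ax[2])
  }
  if (!length(rows))
    return(data.frame(id = integer(), area_um2 = numeric(),
                      major_um = numeric(), minor_um = numeric(),
                      aspect_ratio = numeric()))
  do.call(rbind, rows)
}

#' Count PLA dots per cell
#'
#' Dots are connected components of the dot channel above
#' \code{dotThreshold} within a size band; cells are counted from the nuclei
#' (DAPI) channel by Otsu thresholding and labeling. Returns dots per cell,
#' optionally normalized to a reference condition.
#'
#' @param image PLA dot channel (matrix).
#' @param nucleiImage DAPI channel (matrix).
#' @param dotThreshold intensity threshold for dots.
#' @param sizeBandPx c(min, max) dot area in pixels (default 2-50).
#' @param minNucleusPx minimum nucleus size.
#' @param reference optional reference dots-per-cell for normalization.
#' @return list: dots, cells, dots_per_cell, normalized (NA without
#'   reference).
#' @export
countPlaDots <- function(image, nucleiImage, dotThreshold,
                         sizeBandPx = c(2, 50), minNucleusPx = 20L,
                         reference = NULL) {
  nucMask <- nucleiImage > otsuThreshold(nucleiImage)
  nucLab <- EBImage::bwlabel(nucMask * 1)
  nucSizes <- tabulate(nucLab[nucLab > 0])
  cells <- sum(nucSizes >= minNucleusPx)
  if (cells == 0) mqStop("no_cells", "no nuclei detected")
  dotMask <- image > dotThreshold
  dotLab <- EBImage::bwlabel(dotMask * 1)
  dotSizes <- tabulate(dotLab[dotLab > 0])
  dots <- sum(dotSizes >= sizeBandPx[1] & dotSizes <= sizeBandPx[2])
  dpc <- dots / cells
  list(dots = dots, cells = cells, dots_per_cell = dpc,
       normalized = if (is.null(reference)) NA_real_ else dpc / reference)
}

#' Per-cluster areas of VDAC1-like punctate signal
#'
#' Gaussian blur, MaxEntropy (Kapur) threshold, then watershed on the
#' distance transform to split touching clusters.
#'
#' @param image single-channel 2D matrix.
#' @param sigmaPx Gaussian blur sigma (default 1).
#' @param pxNm optional pixel size; areas are also reported in px^2.
#' @return data.frame: cluster id and area_px2 (and area_nm2 if pxNm given).
#' @export
clusterSizes <- function(image, sigmaPx = 1, pxNm = NULL) {
  blurred <- if (sigmaPx > 0)
    as.matrix(EBImage::gblur(image, sigma = sigmaPx)) else image
  mask <- blurred > kapurThreshold(blurred)
  if (!any(mask))
    return(data.frame(cluster = integer(), area_px2 = numeric()))
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm)
  ids <- sort(unique(as.integer(ws)[as.integer(ws) > 0]))
  out <- data.frame(cluster = seq_along(ids),
                    area_px2 = vapply(ids, function(i) sum(ws == i),
                                      numeric(1)))
  if (!is.null(pxNm)) out$area_nm2 <- out$area_px2 * pxNm^2
  out
}
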