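# Cristae membrane quantification: amount and density from perimeters,
# erosion-based radial density profile, membrane kinetics, MERCs masks and
# the MCU inner-boundary-membrane association index.

#' Cristae membrane amount and density of one mitochondrion
#'
#' Perimeters are estimated by marching-squares boundary tracing at the 0.5
#' level; areas by pixel counting. The cristae/mito perimeter ratio measures
#' cristae membrane amount, the cristae perimeter over mitochondrial area
#' measures cristae density.
#'
#' @param mitoMask,cristaeMask logical matrices; cristae must lie inside the
#'   mitochondrion.
#' @param pxNm pixel size in nm (TEM default 2.94).
#' @return list: mito_area_um2, mito_perimeter_um, cristae_perimeter_um,
#'   cm_amount, cm_density (per um).
#' @export
cristaeDensity <- function(mitoMask, cristaeMask, pxNm = 2.94) {
  if (any(cristaeMask & !mitoMask))
    mqStop("mask_inconsistent", "cristae pixels outside the mitochondrion")
  areaUm2 <- sum(mitoMask) * (pxNm / 1000)^2
  mitoPerUm <- maskPerimeterPx(mitoMask) * pxNm / 1000
  criPerUm <- maskPerimeterPx(cristaeMask) * pxNm / 1000
  list(mito_area_um2 = areaUm2,
       mito_perimeter_um = mitoPerUm,
       cristae_perimeter_um = criPerUm,
       cm_amount = if (mitoPerUm > 0) criPerUm / mitoPerUm else 0,
       cm_density = if (areaUm2 > 0) criPerUm / areaUm2 else 0)
}

#' Radial cristae density profile by iterative erosion
#'
#' The hole-filled mitochondrial mask is eroded in 2-pixel disk increments;
#' each shell is the set difference of consecutive erosions and its cristae
#' coverage is the percentage of shell pixels that are cristae. The raw
#' shell series (outermost first) is linearly interpolated onto 100
#' positions indexed 0 (outermost shell) to 100 (mitochondrial center).
#'
#' @param mitoMask,cristaeMask logical matrices.
#' @param stepPx erosion increment in pixels (default 2; at 2.94 nm/px one
#'   step is 5.88 nm).
#' @return list: \code{rho_cm} (100 values, percent), \code{shell_index}
#'   (positions on the 0-100 scale), \code{raw} (data.frame of per-shell
#'   pixel counts and coverage), \code{holes_filled} flag.
#' @export
radialProfile <- function(mitoMask, cristaeMask, stepPx = 2L) {
  if (any(cristaeMask & !mitoMask))
    mqStop("mask_inconsistent", "cristae pixels outside the mitochondrion")
  filled <- fillMaskHoles(mitoMask)
  holesFilled <- any(filled & !mitoMask)
  shells <- list()
  cur <- filled
  repeat {
    nxt <- erodeDisk(cur, stepPx)
    if (!any(nxt)) { shells[[length(shells) + 1L]] <- cur; break }
    shells[[length(shells) + 1L]] <- cur & !nxt
    cur <- nxt
  }
  K <- length(shells)
  if (K < 3) mqStop("insufficient_shells",
                    sprintf("mask yields only %d shell(s); need >= 3", K))
  raw <- data.frame(
    shell = seq_len(K),
    pixels = vapply(shells, sum, numeric(1)),
    cristae_pixels = vapply(shells, function(s) sum(s & cristaeMask),
                            numeric(1)))
  raw$coverage_pct <- 100 * raw$cristae_pixels / raw$pixels
  xRaw <- (raw$shell - 1) / (K - 1) * 100
  xOut <- seq(0, 100, length.out = 100)
  rho <- approx(xRaw, raw$coverage_pct, xout = xOut, rule = 2)$y
  list(rho_cm = rho, shell_index = xOut, raw = raw, shells = shells,
       holes_filled = holesFilled)
}

#' Cristae membrane kinetics from a binarized movie
#'
#' For each consecutive frame pair, the fraction of pixels changing state
#' (XOR count over the analysis-mask area) measures membrane movement.
#'
#' @param movie logical array (x, y, frame) or list of logical matrices.
#' @param regionMask optional mask restricting the analysis (e.g. MERCs).
#' @return list: movements_per_frame (length n_frames - 1), region.
#' @export
membraneKinetics <- function(movie, regionMask = NULL) {
  if (is.list(movie)) movie <- simplify2array(movie)
  nf <- dim(movie)[3]
  if (is.na(nf) || nf < 2) mqStop("too_short", "need at least 2 frames")
  if (is.null(regionMask)) {
    regionMask <- matrix(TRUE, dim(movie)[1], dim(movie)[2])
    region <- "whole_mito"
  } else region <- "mercs"
  area <- sum(regionMask)
  if (area == 0) mqStop("empty_roi", "analysis mask is empty")
  mv <- vapply(seq_len(nf - 1L), function(k) {
    sum(xor(movie[, , k], movie[, , k + 1L]) & regionMask) / area
  }, numeric(1))
  list(movements_per_frame = mv, region = region)
}

#' MERCs analysis mask from ER and mitochondria masks
#'
#' The ER-mitochondria overlap, dilated by \code{dilationPx} pixels and
#' clipped to the mitochondrial mask.
#'
#' @param erMask,mitoMask co-registered logical matrices.
#' @param dilationPx dilation radius in pixels (default 3).
#' @return logical matrix.
#' @export
mercsMask <- function(erMask, mitoMask, dilationPx = 3L) {
  overlap <- erMask & mitoMask
  if (!any(overlap)) mqStop("no_contact", "ER and mito masks do not overlap")
  dilateDisk(overlap, dilationPx) & mitoMask
}

#' MCU inner-boundary-membrane association index
#'
#' Ratio of the mean MCU intensity in the IBM mask to that in the cristae
#' mask; higher values indicate MCU redistribution from cristae to the IBM.
#'
#' @param mcuImage background-subtracted MCU channel (matrix).
#' @param ibmMask,cristaeMask disjoint, non-empty logical masks.
#' @param eps guard for a near-zero cristae mean.
#' @return list: ibm_mean, cristae_mean, index, flags.
#' @export
ibmAssociation <- function(mcuImage, ibmMask, cristaeMask, eps = 1e-9) {
  if (!any(ibmMask) || !any(cristaeMask))
    mqStop("empty_roi", "IBM and cristae masks must be non-empty")
  if (any(ibmMask & cristaeMask))
    stop("IBM and cristae masks must be disjoint")
  ibmMean <- mean(mcuImage[ibmMask])
  criMean <- mean(mcuImage[cristaeMask])
  if (criMean <= eps)
    mqStop("division_guard", "cristae mean intensity at or below epsilon")
  flags <- character()
  idx <- ibmMean / criMean
  if (idx > 100) flags <- "saturated"
  list(ibm_mean = ibmMean, cristae_mean = criMean, index = idx,
       flags = flags)
}

#' Derive IBM and cristae masks from MICU1/MCU channels
#'
#' Per-channel Otsu: the MICU1 (IBM-resident) mask defines the IBM; the MCU
#' template mask minus the IBM defines the cristae region.
#'
#' @param micu1Image,mcuImage co-registered matrices.
#' @return list of disjoint logical masks \code{ibm} and \code{cristae}.
#' @export
deriveIbmCristaeMasks <- function(micu1Image, mcuImage) {
  ibm <- micu1Image > otsuThreshold(micu1Image)
  tmpl <- mcuImage > otsuThreshold(mcuImage)
  list(ibm = ibm, cristae = tmpl & !ibm)
}
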