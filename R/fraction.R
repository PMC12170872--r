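# Subcellular-fractionation algebra: percentage of AnxA5-like signal in pure
# mitochondria vs cytosol and its split between the OMM leaflets, with
# correction factors for purification loss (K_pl, from cytochrome-C lanes)
# and damaged mitochondria (K_dm, from VDAC1 +/- proteinase K lanes).

#' Fractionation band-intensity sheet
#'
#' @slot I_blot named band intensities for lanes cyto, p_mito, p_mito_PK.
#' @slot D1 named loading dilution factor per lane.
#' @slot D2 named factor compensating for the fraction of the complete
#'   purification process used per lane.
#' @slot K_pl purification-loss factor (cytochrome-C crude to pure).
#' @slot K_dm damaged-mitochondria factor (VDAC1 +/- PK).
#' @export
setClass("FractionSheet",
  representation(I_blot = "numeric", D1 = "numeric", D2 = "numeric",
                 K_pl = "numeric", K_dm = "numeric"),
  validity = function(object) {
    lanes <- c("cyto", "p_mito", "p_mito_PK")
    for (nm in c("I_blot", "D1", "D2"))
      if (!all(lanes %in% names(slot(object, nm))))
        return(sprintf("%s must be named with %s", nm,
                       paste(lanes, collapse = ", ")))
    if (any(object@I_blot < 0)) return("intensities must be >= 0")
    if (any(c(object@D1, object@D2, object@K_pl, object@K_dm) <= 0))
      return("D1, D2, K_pl, K_dm must be > 0")
    TRUE
  }
)

#' Construct a FractionSheet
#'
#' @param I_blot,D1,D2 named (cyto, p_mito, p_mito_PK) or scalar values.
#' @param K_pl,K_dm correction factors.
#' @return a \linkS4class{FractionSheet}.
#' @export
fractionSheet <- function(I_blot, D1 = 1, D2 = 1, K_pl = 1, K_dm = 1) {
  lanes <- c("cyto", "p_mito", "p_mito_PK")
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x))) return(setNames(rep(x, 3), lanes))
    x[lanes]
  }
  new("FractionSheet", I_blot = expand(I_blot), D1 = expand(D1),
      D2 = expand(D2), K_pl = K_pl, K_dm = K_dm)
}

setMethod("show", "FractionSheet", function(object) {
  cat(sprintf(
    "FractionSheet: I = [%s], K_pl = %.3g, K_dm = %.3g\n",
    paste(sprintf("%s %.3g", names(object@I_blot), object@I_blot),
          collapse = ", "), object@K_pl, object@K_dm))
})

#' Scale a band intensity to a comparable amount
#'
#' Amount = I_blot x D1 x D2, with D1 the loading dilution factor and D2 the
#' factor compensating for the fraction of the purification process loaded.
#'
#' @param I_blot band intensity (>= 0).
#' @param D1,D2 factors (> 0).
#' @return scaled amount.
#' @export
scaleBand <- function(I_blot, D1 = 1, D2 = 1) {
  stopifnot(all(I_blot >= 0), all(D1 > 0), all(D2 > 0))
  I_blot * D1 * D2
}

scaledAmounts <- function(sheet) {
  scaleBand(sheet@I_blot, sheet@D1, sheet@D2)
}

clampPct <- function(x) {
  clamped <- x < 0 | x > 100
  list(value = pmin(100, pmax(0, x)), clamped = any(clamped))
}

#' Percent of signal in pure mitochondria vs cytosol
#'
#' Mitochondrial percentage = p_mito / (p_mito + cyto) x K_pl x 100, with the
#' cytosolic percentage its complement (exactly 100 minus the mitochondrial
#' value before clamping). K factors can push the raw value outside [0, 100];
#' it is then clamped with \code{clamped = TRUE} rather than silently
#' truncated.
#'
#' @param sheet a \linkS4class{FractionSheet}.
#' @return list: pct_p_mito, pct_cyto, raw_pct_p_mito, clamped.
#' @export
pctMito <- function(sheet) {
  a <- scaledAmounts(sheet)
  if (a["p_mito"] + a["cyto"] <= 0)
    mqStop("no_signal", "both mito and cyto amounts are zero")
  raw <- unname(a["p_mito"] / (a["p_mito"] + a["cyto"]) * sheet@K_pl * 100)
  cl <- clampPct(raw)
  list(pct_p_mito = cl$value, pct_cyto = 100 - cl$value,
       raw_pct_p_mito = raw, clamped = cl$clamped)
}

#' Split of mitochondrial signal between OMM leaflets
#'
#' The proteinase-K-digested share (cytosolic/outer leaflet) is
#' p_mito / (p_mito + p_mito_PK) x K_dm x 100; the PK-protected
#' (inner-leaflet) share is its complement. A PK lane exceeding the
#' untreated lane beyond tolerance raises a \code{pk_inconsistent} warning.
#'
#' @param sheet a \linkS4class{FractionSheet}.
#' @param tol relative tolerance for the PK consistency check.
#' @return list: pct_outer_leaflet, pct_inner_leaflet, raw_pct_outer,
#'   clamped, flags.
#' @export
pctLeaflet <- function(sheet, tol = 0.05) {
  a <- scaledAmounts(sheet)
  if (a["p_mito"] + a["p_mito_PK"] <= 0)
    mqStop("no_signal", "both +/- PK amounts are zero")
  flags <- character()
  if (a["p_mito_PK"] > a["p_mito"] * (1 + tol)) {
    warning("pk_inconsistent: PK lane exceeds the untreated lane")
    flags <- "pk_inconsistent"
  }
  raw <- unname(a["p_mito"] / (a["p_mito"] + a["p_mito_PK"]) *
                  sheet@K_dm * 100)
  cl <- clampPct(raw)
  list(pct_outer_leaflet = cl$value, pct_inner_leaflet = 100 - cl$value,
       raw_pct_outer = raw, clamped = cl$clamped, flags = flags)
}

#' Purification-loss factor from cytochrome-C lanes
#'
#' Compensates for mitochondrial mass lost between the crude and pure
#' fractions: the factor is the D-scaled crude over pure cytochrome-C amount
#' (>= 1 when material was lost), multiplying the mitochondrial share in
#' \code{\link{pctMito}}.
#'
#' @param I_crude,I_pure cytochrome-C band intensities.
#' @param D1_crude,D2_crude,D1_pure,D2_pure lane scaling factors.
#' @return K_pl.
#' @export
purificationLossFactor <- function(I_crude, I_pure, D1_crude = 1,
                                   D2_crude = 1, D1_pure = 1, D2_pure = 1) {
  stopifnot(I_crude > 0, I_pure > 0)
  scaleBand(I_crude, D1_crude, D2_crude) / scaleBand(I_pure, D1_pure, D2_pure)
}

#' Damaged-mitochondria factor from VDAC1 +/- PK lanes
#'
#' VDAC1 is fully membrane-embedded and PK-protected in intact mitochondria;
#' its loss under PK reflects broken OMMs. The factor is the untreated over
#' PK-treated VDAC1 amount.
#'
#' @param I_noPK,I_PK VDAC1 band intensities without and with PK.
#' @param D1_noPK,D2_noPK,D1_PK,D2_PK lane scaling factors.
#' @return K_dm.
#' @export
damagedMitoFactor <- function(I_noPK, I_PK, D1_noPK = 1, D2_noPK = 1,
                              D1_PK = 1, D2_PK = 1) {
  stopifnot(I_noPK > 0, I_PK > 0)
  scaleBand(I_noPK, D1_noPK, D2_noPK) / scaleBand(I_PK, D1_PK, D2_PK)
}
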