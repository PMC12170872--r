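#' @import methods
#' @importFrom stats aggregate approx coef cor density lm mad median nls
#'   quantile rbinom rexp rlnorm rnorm runif sd setNames var predict resid
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

#' Synthetic-data configuration
#'
#' Holds the acquisition geometry and noise model shared by every synthetic
#' generator. The seed fixes all generated content bit-for-bit: each generator
#' draws from its own substream derived deterministically from \code{seed} and
#' the generator name, so adding a generator never shifts the randomness of
#' another.
#'
#' @slot seed integer master seed.
#' @slot voxelXYnm lateral voxel size in nm (confocal default 65 nm).
#' @slot voxelZnm axial voxel size in nm (default 200 nm, i.e. 0.2 um z-steps).
#' @slot temPxNm TEM pixel size in nm (default 2.94, so a 2-pixel erosion
#'   step equals 5.88 nm).
#' @slot frameIntervalS frame interval in seconds for time-lapse data.
#' @slot gaussianSD additive Gaussian noise SD (intensity units).
#' @slot poissonScale Poisson gain; 0 disables shot noise.
#' @export
setClass("SynthConfig",
  representation(
    seed = "integer", voxelXYnm = "numeric", voxelZnm = "numeric",
    temPxNm = "numeric", frameIntervalS = "numeric",
    gaussianSD = "numeric", poissonScale = "numeric"
  ),
  validity = function(object) {
    if (length(object@seed) != 1L || is.na(object@seed))
      return("seed must be a single non-missing integer")
    lens <- c(object@voxelXYnm, object@voxelZnm, object@temPxNm,
              object@frameIntervalS)
    if (any(!is.finite(lens)) || any(lens <= 0))
      return("all lengths and intervals must be finite and > 0")
    TRUE
  }
)

#' Construct a SynthConfig
#'
#' @param seed integer master seed.
#' @param voxelXYnm,voxelZnm confocal voxel sizes in nm.
#' @param temPxNm TEM pixel size in nm.
#' @param frameIntervalS frame interval in seconds.
#' @param gaussianSD,poissonScale noise model.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(seed = 1)
#' @export
synthConfig <- function(seed, voxelXYnm = 65, voxelZnm = 200,
                        temPxNm = 2.94, frameIntervalS = 2,
                        gaussianSD = 0.02, poissonScale = 0) {
  new("SynthConfig", seed = as.integer(seed), voxelXYnm = voxelXYnm,
      voxelZnm = voxelZnm, temPxNm = temPxNm,
      frameIntervalS = frameIntervalS, gaussianSD = gaussianSD,
      poissonScale = poissonScale)
}

#' Multi-channel 3D image stack with physical voxel sizes
#'
#' @slot channels named list of numeric arrays, all with identical
#'   \code{dim(x, y, z)}.
#' @slot voxelXYnm,voxelZnm voxel sizes in nm.
#' @slot frameIntervalS frame interval (s); \code{NA} for single time points.
#' @export
setClass("ImageStack3D",
  representation(channels = "list", voxelXYnm = "numeric",
                 voxelZnm = "numeric", frameIntervalS = "numeric"),
  validity = function(object) {
    if (length(object@channels) == 0) return("at least one channel required")
    dims <- lapply(object@channels, dim)
    if (any(vapply(dims, length, 1L) != 3L))
      return("channels must be 3D arrays")
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      return("all channels must share dimensions")
    if (object@voxelXYnm <= 0 || object@voxelZnm <= 0)
      return("voxel sizes must be > 0")
    TRUE
  }
)

#' @describeIn ImageStack3D-class channel accessor.
#' @param x an \code{ImageStack3D}.
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
setMethod("getChannel", "ImageStack3D", function(x, name) x@channels[[name]])

#' @describeIn ImageStack3D-class channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
setMethod("channelNames", "ImageStack3D", function(x) names(x@channels))

#' @describeIn ImageStack3D-class voxel sizes as c(xy, z) in nm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
setMethod("voxelSize", "ImageStack3D",
          function(x) c(xy_nm = x@voxelXYnm, z_nm = x@voxelZnm))

setMethod("show", "ImageStack3D", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("ImageStack3D: %d channel(s) [%s], %dx%dx%d voxels, %.0fx%.0f nm\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1], d[2], d[3], object@voxelXYnm, object@voxelZnm))
})

#' Raw dual-channel ratiometric trace
#'
#' Channels are stored in acquisition order: \code{chNum} is the long-emission
#' (530 nm) or 340 nm-excitation channel, \code{chDen} the 480 nm emission or
#' 385 nm excitation channel. The sensor \code{label} decides the ratio
#' orientation downstream (see \code{\link{computeRatio}}).
#'
#' @slot timeS time in seconds, strictly increasing.
#' @slot chNum,chDen intensity vectors.
#' @slot bgNum,bgDen background (scalar or vector, same length as trace).
#' @slot label sensor label, one of matrix, IMS, cristae, cyto_fura,
#'   cyto_gcamp, ER, MICU1_FRET, TMRM.
#' @slot flags character vector of processing flags.
#' @export
setClass("RawTrace",
  representation(timeS = "numeric", chNum = "numeric", chDen = "numeric",
                 bgNum = "numeric", bgDen = "numeric", label = "character",
                 flags = "character"),
  prototype(bgNum = 0, bgDen = 0, label = "matrix", flags = character()),
  validity = function(object) {
    n <- length(object@timeS)
    if (length(object@chNum) != n || length(object@chDen) != n)
      return("time and channels must have equal length")
    if (n > 1 && any(diff(object@timeS) <= 0))
      return("time must be strictly increasing")
    for (bg in list(object@bgNum, object@bgDen))
      if (!(length(bg) %in% c(1L, n)))
        return("length_mismatch: background must be scalar or trace-length")
    TRUE
  }
)

#' Construct a RawTrace
#' @param timeS,chNum,chDen,bgNum,bgDen,label see \linkS4class{RawTrace}.
#' @export
rawTrace <- function(timeS, chNum, chDen, bgNum = 0, bgDen = 0,
                     label = "matrix") {
  new("RawTrace", timeS = as.numeric(timeS), chNum = as.numeric(chNum),
      chDen = as.numeric(chDen), bgNum = as.numeric(bgNum),
      bgDen = as.numeric(bgDen), label = label)
}

setMethod("show", "RawTrace", function(object) {
  cat(sprintf("RawTrace [%s]: %d samples, %.1f-%.1f s, flags: %s\n",
              object@label, length(object@timeS),
              min(object@timeS), max(object@timeS),
              if (length(object@flags)) paste(object@flags, collapse = ",")
              else "none"))
})

#' Derived ratio trace with response metrics
#'
#' @slot timeS time (s).
#' @slot ratio ratio vector (NA where the denominator was non-positive).
#' @slot masked logical vector marking masked samples.
#' @slot basal mean ratio inside the baseline window.
#' @slot peak extremum of the 5-sample moving average outside baseline.
#' @slot delta response amplitude, non-negative by the direction convention.
#' @slot direction "up" (peak - basal) or "down" (basal - nadir).
#' @slot bleachParams per-channel exponential fit parameters (list).
#' @slot baselineWindow integer index range used for the basal value.
#' @slot flags processing flags.
#' @export
setClass("RatioTrace",
  representation(timeS = "numeric", ratio = "numeric", masked = "logical",
                 basal = "numeric", peak = "numeric", delta = "numeric",
                 direction = "character", bleachParams = "list",
                 baselineWindow = "integer", flags = "character"))

setMethod("show", "RatioTrace", function(object) {
  cat(sprintf("RatioTrace: %d samples, basal %.3f, peak %.3f, delta %.3f (%s)\n",
              length(object@ratio), object@basal, object@peak, object@delta,
              object@direction))
})

#' Concentration-response data and Hill fit
#'
#' @slot concUM concentrations (uM), one per observation.
#' @slot response responses, one per observation.
#' @slot fit named list: EC50_uM, hill_n, floor, ceiling, r2, logEC50.
#' @slot ci95 bootstrap 95 percent interval for EC50 (uM).
#' @slot seed bootstrap seed.
#' @slot flags e.g. "poor_fit", "extrapolated".
#' @export
setClass("DoseResponse",
  representation(concUM = "numeric", response = "numeric", fit = "list",
                 ci95 = "numeric", seed = "integer", flags = "character"))

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse: %d obs, EC50 %.3g uM (95%% CI %.3g-%.3g), hill %.2f\n",
              length(object@response), object@fit$EC50_uM,
              object@ci95[1], object@ci95[2], object@fit$hill_n))
})

#' Labeled 3D segmentation
#'
#' @slot labels integer array; 0 = background, objects labeled 1..N.
#' @slot thresholdGlobal global Otsu threshold used.
#' @slot localRadiusNm local-threshold radius (nm).
#' @slot minObjectVoxels minimum object size kept.
#' @slot voxelXYnm,voxelZnm voxel sizes (nm).
#' @export
setClass("SegmentationResult",
  representation(labels = "array", thresholdGlobal = "numeric",
                 localRadiusNm = "numeric", minObjectVoxels = "integer",
                 voxelXYnm = "numeric", voxelZnm = "numeric"),
  validity = function(object) {
    labs <- sort(unique(as.integer(object@labels)))
    labs <- labs[labs != 0L]
    if (length(labs) && !identical(labs, seq_along(labs)))
      return("labels must be contiguous 1..N")
    TRUE
  }
)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d object(s), global threshold %.4g\n",
              max(object@labels), object@thresholdGlobal))
})

#' Immunogold particle field
#'
#' Particle coordinates and outer-mitochondrial-membrane (OMM) contours in nm;
#' optional raster compartment masks (pixel grid at \code{pxNm} nm/px).
#'
#' @slot particles two-column matrix (x_nm, y_nm).
#' @slot contours list of closed polygons, each a two-column matrix in nm.
#' @slot masks named list of logical matrices (mitochondria, nucleus, cytosol).
#' @slot pxNm pixel size of the masks in nm.
#' @slot compartment factor per particle (filled by assignCompartment).
#' @slot signedDnm signed distance to the nearest OMM contour per particle
#'   (positive = matrix side, negative = cytosol side).
#' @export
setClass("GoldParticleField",
  representation(particles = "matrix", contours = "list", masks = "list",
                 pxNm = "numeric", compartment = "factor",
                 signedDnm = "numeric"),
  prototype(compartment = factor(), signedDnm = numeric()),
  validity = function(object) {
    if (ncol(object@particles) != 2) return("particles must be n x 2")
    for (ct in object@contours) {
      if (ncol(ct) != 2 || nrow(ct) < 3) return("contours must be n>=3 x 2")
      if (polygonSelfIntersects(ct)) return("invalid_contour")
    }
    TRUE
  }
)

#' @describeIn GoldParticleField-class particle coordinate accessor.
#' @param x a GoldParticleField.
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
setMethod("particles", "GoldParticleField", function(x) x@particles)

#' @describeIn GoldParticleField-class signed distances (nm) accessor.
#' @export
setGeneric("signedDistances", function(x) standardGeneric("signedDistances"))
setMethod("signedDistances", "GoldParticleField", function(x) x@signedDnm)

setMethod("show", "GoldParticleField", function(object) {
  cat(sprintf("GoldParticleField: %d particles, %d contour(s)%s\n",
              nrow(object@particles), length(object@contours),
              if (length(object@compartment))
                sprintf(", compartments assigned") else ""))
})

#' Mitochondria-attached single-channel recording
#'
#' @slot sweeps list of numeric current vectors (pA).
#' @slot testMV test potential (mV) of each sweep.
#' @slot fsHz sampling rate (Hz).
#' @slot filterHz low-pass corner frequency (Hz).
#' @slot protocol list: hold_mV, test_mV, dur_s, interval_s.
#' @slot day optional day label per sweep-set for occurrence grouping.
#' @export
setClass("SingleChannelRecording",
  representation(sweeps = "list", testMV = "numeric", fsHz = "numeric",
                 filterHz = "numeric", protocol = "list", day = "character"),
  prototype(day = NA_character_),
  validity = function(object) {
    if (length(object@sweeps) != length(object@testMV))
      return("each sweep must be tagged with its test potential")
    if (object@fsHz < 2 * object@filterHz)
      return("sampling rate must be at least twice the filter corner")
    TRUE
  }
)

setMethod("show", "SingleChannelRecording", function(object) {
  cat(sprintf("SingleChannelRecording: %d sweeps at %s mV, fs %.0f Hz, filter %.0f Hz\n",
              length(object@sweeps),
              paste(sort(unique(object@testMV)), collapse = "/"),
              object@fsHz, object@filterHz))
})

#' Idealized single-channel sweep
#'
#' @slot dwells data.frame with columns level (integer open count) and
#'   duration_s; durations sum exactly to the sweep duration.
#' @slot baselinePA baseline (closed) current level, pA.
#' @slot unitaryAmpPA unitary current amplitude, pA (signed).
#' @slot nLevels maximum number of simultaneously open channels observed.
#' @slot openTimeS total level-weighted open time (s).
#' @slot fsHz sampling rate.
#' @slot flags e.g. "silent".
#' @export
setClass("IdealizedSweep",
  representation(dwells = "data.frame", baselinePA = "numeric",
                 unitaryAmpPA = "numeric", nLevels = "integer",
                 openTimeS = "numeric", fsHz = "numeric", flags = "character"))

setMethod("show", "IdealizedSweep", function(object) {
  cat(sprintf("IdealizedSweep: %d dwell(s), amp %.2f pA, open %.3f s%s\n",
              nrow(object@dwells), object@unitaryAmpPA, object@openTimeS,
              if ("silent" %in% object@flags) " [silent]" else ""))
})
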