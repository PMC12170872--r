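# Plain-format I/O: multi-page TIFF stacks with a YAML geometry sidecar,
# CSV tables for traces/sweeps/particles/blots, YAML ground truth.

#' Write an ImageStack3D as multi-page TIFF plus a YAML sidecar
#'
#' Pages are z-slices, channels are written as separate files
#' (\code{<base>_<channel>.tif}); voxel sizes and frame interval go to
#' \code{<base>.yaml}.
#'
#' @param stack an \linkS4class{ImageStack3D}.
#' @param base output path base (no extension).
#' @return invisibly, the files written.
#' @export
writeImageStack <- function(stack, base) {
  files <- character()
  for (nm in channelNames(stack)) {
    arr <- getChannel(stack, nm)
    rng <- range(arr)
    norm <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
    pages <- lapply(seq_len(dim(arr)[3]), function(k) norm[, , k])
    f <- sprintf("%s_%s.tif", base, nm)
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  meta <- list(channels = as.list(channelNames(stack)),
               voxel_xy_nm = stack@voxelXYnm, voxel_z_nm = stack@voxelZnm,
               frame_interval_s = if (is.na(stack@frameIntervalS)) NULL
                                  else stack@frameIntervalS,
               intensity_note = "channels rescaled to [0,1] per channel")
  yf <- paste0(base, ".yaml")
  yaml::write_yaml(meta, yf)
  invisible(c(files, yf))
}

#' Read an ImageStack3D written by writeImageStack
#' @param base path base used when writing.
#' @return an \linkS4class{ImageStack3D}.
#' @export
readImageStack <- function(base) {
  meta <- yaml::read_yaml(paste0(base, ".yaml"))
  channels <- list()
  for (nm in unlist(meta$channels)) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", base, nm), all = TRUE)
    channels[[nm]] <- simplify2array(pages)
  }
  new("ImageStack3D", channels = channels,
      voxelXYnm = meta$voxel_xy_nm, voxelZnm = meta$voxel_z_nm,
      frameIntervalS = if (is.null(meta$frame_interval_s)) NA_real_
                       else meta$frame_interval_s)
}

#' Write a set of raw traces as a long-format CSV
#'
#' Columns: cell, time_s, ch_num, ch_den, label.
#' @param traces list of \linkS4class{RawTrace}.
#' @param path output CSV path.
#' @export
writeTraceTable <- function(traces, path) {
  tab <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(cell = i, time_s = tr@timeS, ch_num = tr@chNum,
               ch_den = tr@chDen, label = tr@label)
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read traces written by writeTraceTable
#' @param path CSV path.
#' @return list of \linkS4class{RawTrace}.
#' @export
readTraceTable <- function(path) {
  tab <- read.csv(path)
  lapply(split(tab, tab$cell), function(d)
    rawTrace(d$time_s, d$ch_num, d$ch_den, label = d$label[1]))
}

#' Write patch sweeps as a long-format CSV
#'
#' Columns: patch, sweep, test_mV, time_s, current_pA.
#' @param recordings list of \linkS4class{SingleChannelRecording}.
#' @param path output CSV path.
#' @export
writeSweepTable <- function(recordings, path) {
  tab <- do.call(rbind, lapply(seq_along(recordings), function(p) {
    rec <- recordings[[p]]
    do.call(rbind, lapply(seq_along(rec@sweeps), function(k) {
      cur <- rec@sweeps[[k]]
      data.frame(patch = p, sweep = k, test_mV = rec@testMV[k],
                 time_s = (seq_along(cur) - 1) / rec@fsHz,
                 current_pA = cur)
    }))
  }))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a GroundTruth record to YAML
#'
#' Array-valued fields (e.g. voxel masks) are summarized by their dimensions
#' and sums rather than dumped.
#'
#' @param truth a GroundTruth (from a synth generator).
#' @param path output YAML path.
#' @export
writeGroundTruth <- function(truth, path) {
  simplify <- function(x) {
    if (is.array(x) || (is.logical(x) && length(x) > 100))
      list(class = class(x)[1], dim = dim(x), sum = sum(x))
    else if (is.function(x)) "<function>"
    else if (is.list(x) && !is.data.frame(x)) lapply(x, simplify)
    else x
  }
  yaml::write_yaml(lapply(unclass(truth), simplify), path)
  invisible(path)
}
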