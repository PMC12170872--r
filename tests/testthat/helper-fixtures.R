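# Shared fixtures, all built in code.

diskMask <- function(n, cx, cy, r) {
  (row(matrix(0, n, n)) - cx)^2 + (col(matrix(0, n, n)) - cy)^2 <= r^2
}

# wrap a binary 3D mask as a SegmentationResult (isotropic unless stated)
segFromMask <- function(mask, voxelXYnm = 100, voxelZnm = 100) {
  lab <- array(0L, dim(mask))
  lab[mask] <- 1L
  new("SegmentationResult", labels = lab, thresholdGlobal = 0,
      localRadiusNm = 640, minObjectVoxels = 1L,
      voxelXYnm = voxelXYnm, voxelZnm = voxelZnm)
}

ellipsoidMask <- function(dim, centre, axes, rot = diag(3)) {
  x <- slice.index(array(0, dim), 1) - centre[1]
  y <- slice.index(array(0, dim), 2) - centre[2]
  z <- slice.index(array(0, dim), 3) - centre[3]
  u <- rot[1, 1] * x + rot[1, 2] * y + rot[1, 3] * z
  v <- rot[2, 1] * x + rot[2, 2] * y + rot[2, 3] * z
  w <- rot[3, 1] * x + rot[3, 2] * y + rot[3, 3] * z
  (u / axes[1])^2 + (v / axes[2])^2 + (w / axes[3])^2 <= 1
}

rotZ <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# noiseless two-state square-pulse sweep: open periods at `amp`
squarePulseSweep <- function(n, openRuns, amp, baseline = 0) {
  cur <- rep(baseline, n)
  for (r in openRuns) cur[r] <- baseline + amp
  cur
}
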