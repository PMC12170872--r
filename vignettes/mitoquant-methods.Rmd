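---
title: "Methods and design of the mitoquant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mitoquant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement models the package implements, the
parameters that matter with their defaults and rationale, the numerical
choices made where a published description leaves the arithmetic open, what
the synthetic-data generators do and do not emulate, and the known
limitations. Everything empirical stated here is computed by the test suite
or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

# Ratiometric trace processing

A raw trace holds two acquisition channels (`chNum` = 530 nm emission or
340 nm excitation, `chDen` = 480 nm emission or 385 nm excitation), their
backgrounds, and a sensor label. Processing is a fixed order:
`subtractBackground()` → `correctBleach()` → `computeRatio()`.

**Background.** Scalar or per-sample vector, subtracted per channel.
Negative corrected values are allowed (they carry noise information) and
flagged; an identically zero channel triggers a warning.

**Bleach correction.** Both emission channels of a FRET/GEM sensor bleach
together; we fit $y = A e^{-t/\tau} + C$ on the basal (pre-stimulus) window
per channel by Levenberg–Marquardt with non-negativity bounds on $A$ and
$C$, then divide the whole trace by the fitted curve normalized to its
first-sample value, so the baseline becomes flat while absolute scale is
preserved. Two deliberate choices:

* The offset $C$ exists in the model because real recordings can retain a
  residual (autofluorescence, incomplete background). For
  background-subtracted data the bleaching is purely multiplicative, and a
  free offset trades off against $\tau$ over short basal windows (the
  window covers only ~1 of $\tau$); `assumeZeroOffset = TRUE` pins $C = 0$
  and is what the τ-recovery test uses. With the offset free, recovering a
  120 s τ from a 150 s basal phase at SNR 20 is only reliable after pooling
  cells.
* A non-convergent fit falls back to a straight line with the flag
  `bleach_linear_fallback` — a trace is never silently left uncorrected.

**Ratio conventions.** The numerator is chosen per sensor so a Ca²⁺ rise is
positive-going for every label: FRET sensors (`matrix`, `ER`,
`MICU1_FRET`) use 530/480, GEM-GECO sensors (`IMS`, `cristae`,
`cyto_gcamp`) use 480/530 (the Ca²⁺-bound species emits at the shorter
wavelength), Fura-2 uses 340/385. The convention is overridable via the
`numerator` argument. Samples with a non-positive denominator are masked;
if more than 10% of samples are masked the ratio is refused
(`ratio_unreliable`) rather than returned misleadingly.

**Response metrics.** The basal value is the mean ratio inside the
baseline window (default: first 60 s, or all pre-stimulus samples if
shorter; stimulus onset is configuration, not detection). The peak is the
extremum of a 5-sample moving average — robust to single-frame noise at the
2–3 s frame intervals typical for these sensors — and `direction = "down"`
handles store-depletion readouts where the response is a drop. Because the
peak is defined on the smoothed trace, the synthetic transient uses a
finite rise time (default 15 s, the scale of agonist-induced mitochondrial
Ca²⁺ rises) with the shape normalized so `transient_amp` is the true peak
amplitude; an instantaneous rise would be systematically shaved by any
noise-robust peak estimator.

**TMRM.** Membrane potential is the per-frame ratio of mean
background-subtracted mitochondrial to nuclear intensity; the experimental
protocol this mirrors records ~2 min of baseline and then 4 min of 1 µM
FCCP perfusion, and `fccpFrame` marks the depolarized plateau.

**Hill fits.** Four-parameter logistic on log₁₀ concentration fitted by
Levenberg–Marquardt, with starts from the per-concentration means, slope
bounded to [0.05, 20], and $EC_{50}$ bounded to within 3 decades of the
tested span (values outside the span are flagged `extrapolated`). The 95%
CI is a seeded case-resampling bootstrap within concentration groups
(default B = 1000); bootstrap rather than profile likelihood because the
per-cell noise is heteroscedastic and multiplicative. Flat data are
refused (`degenerate_response`); fits with R² < 0.5 are flagged
`poor_fit`, not hidden.

# 3D segmentation and morphometry

**Background.** Per-slice grayscale opening with a disc (default radius
50 px, configurable — no radius is canonical) serves as the rolling-ball
background estimate; the opened image is subtracted before thresholding.

**Thresholds.** The global threshold is Otsu's criterion on the full stack
histogram (256 bins). The local threshold is a per-pixel Otsu within a
circular window (default radius 640 nm) computed per slice via one box-sum
pass per histogram bin (64 bins). Local Otsu has a known failure mode:
a window wholly inside one intensity class still gets split at an arbitrary
level. Two guards handle it: windows whose local dynamic range is below
half the stack's range defer to the global threshold, and the two masks are
merged by logical AND — the global mask suppresses the spurious local
foreground that per-slice thresholding produces in empty slices.

**Labeling and measures.** 26-connectivity in 3D (8 in 2D); objects below
`minObjectVoxels` (default 10) are removed, and labels are contiguous.
Volume is voxel count × voxel volume. Surface sums exposed voxel faces
with their true anisotropic areas — on a digitized sphere of radius 10 px
the volume is within 3% of $\frac{4}{3}\pi r^3$ (asserted in tests); the
face-count surface overestimates smooth surfaces by up to ~1.5× and is
reported as the reproducible voxel-surface convention, not a smooth-surface
estimate. Ellipsoid axes come from the eigenvalues $\lambda_i$ of the
second-moment matrix of voxel coordinates in physical units, with semi-axes
$a_i = \sqrt{5\lambda_i}$ (the uniform solid ellipsoid convention), giving
elongation $a/b$ and flatness $b/c$; the branching index is
$V / (\frac{4}{3}\pi abc)$, documented explicitly because the plugin
convention it mirrors is unpublished. Tests pin branching ≈ 1 for
ellipsoids and branched < tube at equal volume. Objects touching the stack
border are flagged `truncated` rather than dropped.

**2D SIM morphology.** Yen's threshold binarizes; per-object area and
moment-derived major/minor axes give the aspect ratio. **PLA**: dots are
connected components above a user threshold inside a size band (default
2–50 px², the published description states only that a threshold was set);
cells are counted from the DAPI channel by Otsu + labeling.
**Clusters**: Gaussian blur (σ default 1 px) → Kapur maximum-entropy
threshold → watershed on the distance transform.

All three histogram thresholds (Otsu, Yen, Kapur) are implemented
in-package on fixed-bin histograms — the installed image library provides
neither Yen nor Kapur and restricts Otsu to [0,1]-ranged 2D images — and
each is verified against an independent brute-force criterion search in
the tests.

# Cristae quantification

**Perimeters** are traced by marching squares (contour at level 0.5 on the
padded mask) and summed as polyline length. On curved boundaries this
estimator carries a small upward bias (~6% on a digitized circle, asserted
in tests); it is used consistently for both mitochondrial and cristae
outlines, so the cm-amount ratio is nearly bias-free. Areas are pixel
counts. The TEM pixel size defaults to 2.94 nm/px so one 2-px erosion step
is exactly 5.88 nm.

**Radial profile (ρCM).** The mitochondrial mask is hole-filled (so the
"center" is geometrically defined), then iteratively eroded with a disc of
radius 2 px — a disc for isotropy, since the published description fixes
only the 2-px increment. Shell $k$ is the set difference of consecutive
erosions; the final non-empty core counts as the last shell. Coverage is
cristae pixels / shell pixels × 100. The raw shell series is mapped
linearly by shell number onto [0, 100] (0 = outermost, 100 = center) and
interpolated to exactly 100 positions. Invariants asserted exactly: shells
are pairwise disjoint, their union is the filled mask, and
$\sum_k (\text{cristae pixels in shell }k)$ equals the total cristae count.
Masks eroding away in fewer than 3 shells are refused
(`insufficient_shells`).

**Kinetics** are the per-frame-pair fraction of pixels changing state (XOR
count over mask area) — symmetric in frame order by construction. The
MERCs analysis mask is the ER∩mito overlap dilated by 3 px (exposed
parameter; the source wording fixes only that the overlap is "partially
dilated") and clipped to the mitochondrion. The IBM association index is
the mean-intensity ratio IBM/cristae with a division guard; the IBM and
cristae masks derive from per-channel Otsu of the MICU1-YFP and MCU-mCherry
channels, with the cristae template minus the IBM to keep them disjoint.

# Immunogold statistics

Compartment assignment is point-in-raster-mask with priority mitochondria >
nucleus > cytosol on boundary ambiguity; particles outside every mask are
reported as `unassigned`, never dropped. Distances are computed
analytically — point-to-segment minimum over the polygonal OMM contour —
for nm precision, with the sign from an even-odd point-in-polygon test
(positive = matrix side). The raster distance transform appears only as a
test oracle (agreement within one pixel is asserted). Particles inside the
nucleus get `NA` distances: near-membrane statistics are defined for
cytosolic and mitochondrial particles only. Occurrence histograms use
10 nm bins (no published bin width) and report the fraction within the
20 nm OMM vicinity window.

# Fractionation algebra

Scaled amounts are $I_{blot} \cdot D_1 \cdot D_2$ per lane (one scaling
rule for every lane, with lane-specific factors; the two published scaling
definitions are typographically identical). The mitochondrial percentage
is $\frac{A_{p.mito}}{A_{p.mito}+A_{cyto}} \cdot K_{pl} \cdot 100$ with the
cytosolic percentage its exact complement; the leaflet split replaces the
cytosol lane with the +PK lane and $K_{pl}$ with $K_{dm}$, the digested
share being the cytosolic-leaflet fraction. $K$ factors can push a raw
percentage outside [0, 100]; values are clamped with an explicit `clamped`
flag to keep the correction auditable. `purificationLossFactor()` computes
$K_{pl}$ as the D-scaled crude/pure cytochrome-C ratio — ≥ 1 when material
was lost, so multiplying the mitochondrial share compensates the loss;
defining it the other way round (pure/crude ≤ 1) would deepen rather than
correct the underestimate. $K_{dm}$ is analogously the VDAC1 −PK/+PK
ratio. A +PK lane exceeding its untreated lane beyond 5% is flagged
`pk_inconsistent`.

# Single-channel analysis

**Idealization.** The closed level and noise are estimated from the
all-points histogram: noise σ from the median absolute lagged difference
(lag = fs/f_c samples, because adjacent samples of 1 kHz-filtered data are
correlated and lag-1 differences understate σ); conductance levels as
kernel-density modes at least 3σ apart, with the bandwidth floored at the
density-grid resolution so near-noiseless recordings remain resolvable.
With inward openings the baseline is the most positive accepted mode — at
high open probability the open mode can dominate the histogram, so "the
tallest mode" would be wrong. The unitary amplitude is the open mode
nearest the baseline among modes beyond 3.5σ, ignoring minor density bumps
from filter-smeared transition ramps (below 25% of the largest candidate).
Transitions are half-amplitude crossings with a ±10% hysteresis band;
events shorter than 1.8× the filter rise time (≈0.6 ms at 1 kHz) are merged
into their neighbours. The amplitude is then re-estimated from level means
excluding samples near transitions. A sweep with no resolvable open mode
idealizes as silent — a valid result with zero open time. Dwell durations
sum to the sweep duration exactly, by construction.

**Statistics.** NPo is level-weighted open time over total time, pooled
across sweeps at one potential (multi-level aware). N is estimated as the
maximum number of simultaneously open levels observed — the only estimate
available without independent channel counting, and a documented
limitation: Po = NPo/N is a lower bound on true single-channel Po whenever
silent channels are present. Occurrence is the percentage of patches with
at least one resolved opening at any potential, grouped by day labels when
present. Conductance is the least-squares slope of mean unitary current vs
potential (pA/mV × 1000 = pS), needing ≥ 3 potentials
(`underdetermined` otherwise), with a bootstrap CI over sweeps. Voltage
signs are stored as given, relative to the inner membrane surface.

# The synthetic generators

All generators draw from substreams derived deterministically from the
master seed and the generator name, so the same seed reproduces every
dataset bit-for-bit and adding a generator never shifts another's
randomness. Every generator returns a `GroundTruth` record; recovery tests
read only generated data plus that record.

What they emulate — and what they do not:

* **Stacks**: tubes, ellipsoids and Y-branched tubes at 65/200 nm voxels
  with two-level intensity, uniform or centrally concentrated internal
  texture, and additive Gaussian noise. No PSF, no SIM striping, no
  shot-noise camera model: segmentation tests therefore probe threshold
  logic and geometry, not deconvolution robustness.
* **Traces**: multiplicative exponential bleaching applied identically to
  both channels (conservative: the ratio is bleach-insensitive while single
  channels still need correction), a finite-rise transient on the
  label-appropriate numerator channel, Gaussian noise relative to channel
  baseline (0.05 = SNR 20).
* **Sweeps**: two-state Markov gating per channel (mean open time 10 ms),
  Boltzmann Po(V) rising with hyperpolarization, unitary current
  $i = \gamma(V - V_{rev})$ with $V_{rev} = 0$ (symmetric solutions),
  Gaussian noise at 0.15× the unitary amplitude added at 10 kHz and then
  4-pole Butterworth-filtered at 1 kHz — noise enters before the filter, as
  in a real rig. No capacitive transients, no baseline drift, no 50 Hz.
* **Gold fields**: a circular OMM polygon (256 vertices) inside a raster
  cell with nucleus; near-membrane particles at Gaussian signed normal
  offsets, the rest scattered uniformly. No clustering of label, no
  section-thickness effects.
* **Fraction sheets**: intensities constructed by algebraic inversion so
  the formulas return the requested split exactly (noiseless) or within
  the stated lognormal CV.
* **Dose–response sets**: per-cell responses from the Hill curve with
  mean-preserving multiplicative lognormal noise.

Passing tests on these data demonstrate that the measurement procedures
recover known truth under the stated noise models; they do not certify
performance on real micrographs or recordings with structured artifacts.

# Problem sizes and runtime choices

The test suite uses stacks of 48–72 px per side with 16–32 slices, 10–20
cells per trace set, 60 s of simulated channel time per NPo estimate (20
seeds per open probability for the bias bound), 120–400 gold particles,
and bootstrap sizes of 199–500 inside tests (1000 in the acceptance
script). These sizes keep the full suite around two minutes on one CPU
while leaving every statistical bound with comfortable margin; all were
chosen as the smallest sizes at which the tested quantity's Monte-Carlo
error is several times tighter than the asserted tolerance.

# Known limitations

* The local Otsu mask is computed per slice (as in the macro it mirrors),
  so strongly anisotropic structures spanning slices see no 3D local
  context.
* The marching-squares perimeter has a small positive bias on curved
  boundaries; ratios of perimeters largely cancel it, absolute perimeters
  retain it.
* N (channel count) from maximum simultaneous openings underestimates when
  channels are silent or Po is very low; Po(V) inherits that bias.
* The bleach model is single-exponential; strongly bi-exponential bleaching
  will leave curvature in the corrected baseline (visible in the recorded
  fit parameters).
* `runStage()` orchestrates the stages on synthetic inputs for
  reproducible end-to-end runs; applying the pipeline to real data means
  calling the stage functions directly on imported TIFF/CSV inputs.
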