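---
title: "Nanoscale mitochondrial morphometry: models, parameters, and validation"
author: "mitomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoscale mitochondrial morphometry: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The measurement problem

STED nanoscopy of neurons whose outer mitochondrial membrane (OMM) is
labeled resolves individual mitochondria as *hollow* tubular or vesicular
outlines: a perpendicular cross-section through a tubule shows the two
membrane walls as two intensity peaks. At this resolution a population of
small OMM-positive objects becomes measurable — mitochondrial-derived
structures (MDSs), operationally defined as objects with area below
$A_{th} = 0.086\ \mu m^2$, a superset that contains mitochondrial-derived
vesicles, fragments, and small mitochondria. `mitomorph` quantifies this
imagery: per-object area, width, and length; MDS and vesicle/stick
classification; per-image functional (+/−) calling from a second channel;
process-length–normalized densities; pulse-chase turnover in concentric
rings; protrusion placement; and contact-site linear densities. A
synthetic image generator with complete ground truth drives every
validation claim in the test suite.

## The image model behind the simulator

Each object is a capsule (stadium) of tip-to-tip length $L$ and outer
width $W$; only its *outline* carries label. The membrane is rendered as a
Gaussian ridge of the radial coordinate, $\exp(-(d - W/2)^2 / 2\sigma_m^2)$
with $d$ the distance to the capsule centreline, then convolved with an
isotropic Gaussian PSF and scaled to the photon budget. Noise is Poisson
shot noise on the counts followed by Gaussian read noise.

Key defaults, fixed once:

* **Pixel pitch 25 nm**, within the 20–30 nm range appropriate for STED
  sampling.
* **PSF sigma 25 nm** (≈ 59 nm FWHM), at the coarse end of a 40–60 nm FWHM
  effective resolution.
* **Membrane ridge FWHM 60 nm** ($\sigma_m \approx 25$ nm). This is the
  *apparent* membrane thickness: a ~7 nm bilayer plus the 10–15 nm
  fluorophore displacement of self-labeling tag + linker on each side,
  plus residual blur. With this value the forward model reproduces the
  qualitative resolution behaviour seen in real data: membrane pairs are
  cleanly bimodal at widths ≥ 120 nm and merge into a single peak below
  ~75 nm, so narrow vesicles present single-peak profiles.
* **Photon budget**: ridge peak 150 counts over a background of 5, read
  sigma 3. Acquisition counts are a free choice of the simulator, not a
  literature value.
* **Geometry**: widths log-normal around a ~140 nm mode (clipped to
  80–500 nm), lengths log-normal up to 4 µm; MDS areas log-normal around
  a 0.035 µm² mode, below $A_{th}$; a configurable fraction of MDSs are
  round vesicles (aspect ratio 1), the rest tubular sticks (aspect ratio
  < 0.5).
* **Placement**: objects sit along piecewise-linear neurite paths
  radiating from a central soma disk, with a minimum edge-to-edge gap of
  300 nm. Gaps below the PSF scale would make two planted objects one
  object in any physically faithful image, so ground-truth counts would
  be unrecoverable *in principle*; 300 nm keeps neighbours separable
  while still crowding objects along neurites.
* **Functional brightness**: positive objects draw their per-object
  brightness from $\mathcal{N}(200, 25)$, negative ones from an
  exponential background with mean 20 — the same two-component family the
  threshold model fits.
* **Pulse-chase**: each object splits a fixed label budget between "old"
  and "new" channels according to a planted ratio that declines linearly
  with radial distance from the soma edge.
* **Protrusions** are short capsules (100 nm neck, 250 nm long) planted on
  tubule boundaries; where membranes meet, the pre-PSF ridge canvas is
  capped at 1 — fused membranes are one continuous surface, not a doubled
  label density.

What the generator does **not** emulate: cristae substructure, 3-D
geometry and defocus, curved or branched mitochondria, object motion,
bleaching, and spatially varying labeling efficiency. Passing tests
therefore demonstrate correctness of the measurement pipeline under the
stated image model, not robustness to every property of real acquisitions.

## Segmentation

Two binarization routes are provided. The **global** route thresholds at a
fixed count level or derives one with the triangle rule (the histogram
point maximally distant from the peak-to-tail chord). The **local Bernsen**
route computes min/max over a disk (default radius 9 px) per pixel; pixels
whose local contrast reaches the gate (default 15 counts) threshold at the
local midgray, and low-contrast pixels are assigned by comparing the local
midgray against the global half-range, strictly, so uniform regions fall
to background. Both defaults sit just inside the "< 10 px" / "< 15"
bounds within which the local method is typically operated on this kind
of data, and both are configurable.

Refinement is an ordered list of morphological steps (3×3 cross unless a
disc is requested). The default recipes strip the *PSF halo*: a threshold
contour sits where the blurred ridge crosses the threshold, i.e. 1–3 px
*outside* the membrane centreline, which for objects a few pixels wide
nearly doubles the apparent area. After `fill_holes`, two cross erosions
(Bernsen route) or one disc-3 erosion (global triangle route, whose lower
auto-threshold leaves a wider halo) return the mask to the geometric
footprint; on simulated fields the summed mask area then lands within
~12% of the planted footprint area and object counts are exact. The
erosion count is an optics-derived default (halo width ≈
$\sigma_{eff}\sqrt{2\ln(\mathrm{peak}/t)}$), not a universal constant: at
other pixel sizes or thresholds it should be re-derived, and the pipeline
exposes it as configuration.

## Morphometry

Connected components are 8-connected (particle-analysis convention).
Ellipse parameters come from the normalized second central moments (with
the 1/12 single-pixel extent term), rescaled so the ellipse area equals
the component area; angles are reported in $[-90°, 90°)$ with y up and
0-based pixel centres as the coordinate origin.

Lengths are measured twice. The skeleton length sums Euclidean steps (1 or
$\sqrt2$ px) over the thinned component; thinning uses a Zhang–Suen
fixed-point check so that already-thin curves pass through exactly, and
Guo–Hall thinning for thick shapes (plain Zhang–Suen leaves 2-px diagonal
staircases on oblique bars). The selected length follows the area gate:
below $A = 0.2\ \mu m^2$ the ellipse major axis is used (skeletons of
small, cap-dominated objects under-cover their length); at or above it,
the longer of the two. Two deterministic biases are worth knowing:

* the moment ellipse of an elongated capsule is ≈ 11% longer than its
  tip-to-tip length (rectangle limit $4/\sqrt{12}$ with area rescale), so
  very elongated tubules (aspect ≳ 18) carry a +10–12% length bias;
* skeleton staircases at shallow angles inflate branch length by a few
  percent relative to the Euclidean axis.

For uses that need an unbiased tip-to-tip estimate of a straight tubule —
e.g. placing protrusion anchors on the quarters scale —
`object_axial_extent()` projects the pixel set onto the fitted axis
instead.

Classification: MDS iff $A < A_{th}$ (boundary to mitochondrion); aspect
ratio $AR = W/L$ with the fitted centre width $W_m$ when an accepted fit
exists, otherwise the ellipse minor axis; vesicle iff $AR \ge 0.5$
(inclusive), stick below. Defining AR as width over length (not its
reciprocal) is the convention under which the 0.5–1 vesicle band is
meaningful; near-circular vesicles whose measured width marginally
exceeds their length are clamped to $AR = 1$ and flagged. Boundary
conventions ($A = A_{th}$, $A = 0.2$, $AR = 0.5$, $L = 2.1\ \mu m$,
distance = ring width, axial fraction 0.25) are each resolved explicitly
in the function contracts and tested.

## Widths from line profiles

Three 0.75-µm profiles are drawn perpendicular to the object axis — at the
centre and near both ends (at $L/6$ and $5L/6$ for $L < 2.1$ µm, at
350 nm from each tip for longer objects) — each bilinearly sampled at
1-px steps and averaged over 5 parallel lines. Peaks are local maxima
with prominence at least 10% of the profile dynamic range and at least
2 samples apart; equal-height twin maxima whose connecting valley is
shallower than the prominence gate merge into one peak.

The fit decision tree: one peak → single Gaussian + constant baseline,
width = FWHM $= 2\sqrt{2\ln 2}\,\sigma$; two peaks → double Gaussian +
baseline (independent sigmas by default, shared optional), width =
centre distance; three or four peaks → likely two objects side by side,
width = mean adjacent peak distance, flagged and excluded from non-width
statistics; more than four peaks, a fit $R^2$ below 0.80 (configurable),
or a non-convergent fit → rejected with a reason code. The baseline term
absorbs residual background after masking. Fits run through
Levenberg–Marquardt (`minpack.lm::nls.lm` on the residual function, which
also handles the zero-residual noise-free case). Initialization comes
from the detected peak positions and heights.

The single-Gaussian branch *knowingly overestimates* the width of
unresolved membrane pairs — the merged profile is wider than either wall.
It is still the best available estimate there, and dropping those objects
would bias the cohort far more; the calibration table
(`analysis/03_width_calibration.R`) quantifies the effect (80-nm objects
read ≈ 150 nm) while resolvable widths (≥ 120 nm) recover with sub-nm
mean bias under the default photon budget.

$W_m$ is the centre width, $W_o$ the mean of accepted end widths; a
rejected centre fit fails the object's width QC. The width ratio
$W_o/W_m$ is reported per object.

## Functional calling

Per-object mean intensities of a functional channel (TMRE, MitoSOX,
lysosome, or any marker) are histogrammed per image (Freedman–Diaconis
bin width, floored at 12 bins) and fitted with
$f(x) = a e^{-bx} + A e^{-(x-\mu)^2/2\sigma^2}$ — exponential background
plus Gaussian signal. The threshold $t^*$ is the argmin of $f$ on
$(0, \mu)$ on a dense grid; the intersection point of the two components
is computed alongside as a diagnostic, since the two operationalizations
of "the minimum between the peaks" can differ slightly and the argmin is
taken as authoritative. If the fit fails or is unimodal the threshold
falls back to Otsu's rule on the means, flagged. Calls are strict
comparisons (+ iff mean > $t^*$), made per image so that acquisition
differences between images never mix. Initialization: decay rate from the
lower-quartile mean, Gaussian centre/width from the upper-half mode. At
least 30 objects (configurable) are required for a fit.

## Spatial statistics

The **process map** recovers neurite length from residual background
fluorescence: soma zeroing, capping at the 99.5th-percentile intensity,
triangle binarization, removal of components < 20 px, 20 dilations, 15
erosions, largest component, skeletonization, branch-length sum. The cap
quantile is the one free parameter; the rest follows the fixed sequence.
Number densities divide per-class counts by this length.

**Turnover** is the refreshment ratio
$R = \Sigma_{new} / (\Sigma_{old} + \Sigma_{new})$ over each object's
pixels (0/0 excluded with a log entry), aggregated in concentric rings of
30 µm measured from the *soma boundary* (not centroid) via a distance
transform, half-open intervals $[30k, 30(k+1))$; objects inside the soma
are excluded. Ring aggregation is object-averaged (pixel-weighted
aggregation would weight large mitochondria more; object averaging keeps
MDSs and mitochondria comparable and the two are reported separately). An
optional proximal normalization divides a single-channel intensity by the
ring-0 mean.

**Protrusions**: the anchor is projected onto the parent axis; axial
fractions in $[0, 0.25] \cup [0.75, 1]$ are "tip" (boundaries inclusive
to the extremities), the middle half "side". Marker positivity uses mean
footprint intensity $>$ background mean $+ 2$ SD; the background reference
is the neurite filament signal outside labeled structures, and $k = 2$ is
a documented default where only "compared with background" is specified.

**Contact sites**: a punctum contacts a mitochondrion when its
boundary-to-boundary distance is at most a configurable reach (default
0 nm = overlap or 8-adjacency, implemented by dilating the mitochondrial
mask one box pass plus one per pixel of reach); the linear density divides
contacting puncta by summed selected lengths.

## Validation strategy and problem sizes

Every stage is tested against an *independent* oracle rather than against
itself: Bernsen against a brute-force per-pixel evaluation of the rule
(exact on ≤ 64×64 instances), ellipse fits against an eigendecomposition
of the covariance matrix (≤ 10⁻⁶ relative), Gaussian fits against a
coarse-grid + Nelder–Mead least-squares search (≤ 2 nm noise-free),
rendered cross-sections against a dense 1-D convolution of the forward
model, and the threshold against the analytic valley of the planted
mixture density. Cohort-level checks use 50 replicates per width at
120–300 nm (mean bias < 10 nm, rejections < 5%), 20 seeded draws of a
500-object intensity mixture (median valley error below half a histogram
bin; called positive fractions inside binomial 99% bounds), and a
noise-free 77 × 77 µm field with 30 mitochondria, 20 MDSs, 12 protrusions
and a planted turnover gradient (exact object count, diagonal
class/shape confusion matrices, tip fraction within binomial bounds,
per-ring turnover means within 0.05 of the planted line). These sizes
keep the full suite under a few minutes on one core while leaving each
statistical bound comfortably powered.

## Known limitations

* Lengths of very elongated tubules inherit the +11% moment-ellipse bias
  discussed above; comparisons *between* conditions are unaffected
  (the bias is monotone and consistent), absolute lengths of
  high-aspect objects are not.
* Widths below the merge separation (~75 nm at the default optics) are
  reported from single-Gaussian FWHM and are overestimates by
  construction.
* The Bernsen tie rule for low-contrast pixels (global half-range
  comparison) is one of several reasonable choices; it is switchable and
  recorded in mask provenance.
* Erosion-based halo stripping assumes the imaging PSF of the defaults;
  other optics need a re-derived count.
* The per-image threshold model assumes a unimodal background and a
  single positive population; strongly trimodal intensity distributions
  will fall back to Otsu and should be inspected.
* Ring statistics assume the soma mask is a single compact region; a
  fragmented soma mask shifts the distance origin.
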