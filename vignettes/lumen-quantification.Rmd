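---
title: "Quantifying vessel lumina along relaxation-stabilized centerlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vessel lumina along relaxation-stabilized centerlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenline)
```

## The problem

Atherosclerotic arteries deviate strongly from a cylinder: they bend, they
carry local constrictions (plaque) and swellings, and they bifurcate. Given
an isotropic 3D tomogram of such a segment, the quantity of biomechanical
interest is the lumen cross-sectional area measured in planes orthogonal to
the vessel's own course — not orthogonal to the scanner's z-axis. Counting
foreground per z-slice overestimates the area of a tube tilted by an angle
$\theta$ by $1/\cos\theta$ (15.5 % at 30°), so an accurate centerline with
reliable tangents is the crux of the measurement.

`lumenline` implements the full chain: segmentation preprocessing of the
grayscale tomogram, an iterative relaxation-stabilized centerline estimator
on the binary lumen, area profiling along that centerline, station-wise
shrinkage between two preparation states of the same vessel, and
joint-histogram comparison of two registered imaging modalities. A phantom
generator with analytic ground truth makes every stage testable without any
image data.

## The centerline estimator

`centerline_fit()` treats the centerline as the fixed point of a
recenter-and-relax map. With the lumen mask loaded as a stack of x–y slices
(isotropic voxels, z along the vessel):

1. **Initialization.** For every z-slice the centroid of the foreground
   voxels gives $c_{0,k}$, $k = 1,\dots,N_k$; interior empty slices are
   bridged by linear interpolation and the three coordinate sequences are
   smoothed with a Gaussian of width $\sigma$ (default 20 samples). For a
   lumen parallel to z this initial curve is already the answer and the
   iteration stops at its first residual check.
2. **Tangents.** Unit tangents $\tau_{i,k}$ by second-order finite
   differences: central differences inside, the one-sided stencil
   $(-3f_1 + 4f_2 - f_3)/2$ at the ends. Both are exact on quadratic
   curves, which the unit tests exploit.
3. **Orthogonal resampling.** The mask is interpolated trilinearly on a
   square grid in the plane through $c_{i,k}$ with normal $\tau_{i,k}$
   (spacing 1 voxel; half-extent 1.5× the largest per-slice bounding-box
   half-diagonal, so a section can never clip the lumen).
4. **Recentering.** The resampled slice is thresholded at 0.5 — the
   trilinear midpoint of a binary edge — labelled into 8-connected
   components, and the component nearest the current point is selected;
   its centroid, mapped back to 3D, is the recentered point $c_{j,k}$.
   Components cut from a bifurcation appendage are thereby ignored once
   they separate from the main lumen in-plane.
5. **Relaxation.** $c_{i+1,k} = (1-\beta)\,c_{j,k} + \beta\,c_{i,k}$,
   followed by the same Gaussian smoothing along $k$. The relaxation
   weight $\beta$ (default 0.5; 0.9 for debris-contaminated masks)
   stabilizes the update where oblique slices would otherwise overshoot.
6. **Termination.** The residual
   $\rho = \sum_k d(c_{i,k}, c_{i+1,k})/N_k$ — the mean point
   displacement in voxel lengths — is recorded each iteration; the loop
   ends when $\rho < \mu$ (default 0.3 voxel) or at `max_iter` (default
   100, far above the worst case we observe). Non-convergence warns and
   returns the last iterate flagged `converged = FALSE`.

The returned `centerline_fit` object keeps every intermediate centerline
and the residual history, and has `print`, `summary`, `plot`, `residuals`,
`coef` and `predict` methods.

### Numerical choices worth knowing

* **Curve smoothing boundary.** The coordinate sequences are extended by
  antisymmetric (point) reflection about the end values before Gaussian
  smoothing. This preserves constant *and linear* sequences exactly, so a
  straight centerline is a true fixed point; plain symmetric reflection
  would contract the z-ramp at the ends on every pass and the straight
  cylinder would never stop moving. The kernel radius is
  $\min(\lceil 3\sigma \rceil, N_k - 1)$.
* **Stack-face boundary.** During slice extraction the mask is extended
  beyond the two z faces by replicating the face slices: a vessel crossing
  the imaged volume continues beyond it, and without the extension an
  oblique end slice cuts into void and drags the end points several voxels
  inward. Stations within about one slice half-extent of a face still feel
  the (straight) continuation model, which is why phantom accuracy checks
  evaluate interior stations.
* **Index correspondence.** Point $k$ of iteration $i+1$ descends from
  point $k$ of iteration $i$; there is no re-parameterization by arclength
  between iterations, which keeps the residual well defined point-wise.
* **Ties.** Among equidistant candidate components the larger one wins.
  Samples interpolating to exactly 0.5 count half (midpoint rule); a hard
  $\ge 0.5$ rule would dilate an integer-radius section by a quarter
  sample at sub-voxel sampling and bias areas by several percent.
* **$\sigma$ is per-index, not per-arclength.** Stations are one voxel
  apart in z at initialization and stay close to that spacing, so the
  distinction is minor; it is stated here because curvature makes the two
  parameterizations drift slowly apart.

## Cross-section and shrinkage profiles

`area_profile()` extracts, at every final station, the plane orthogonal to
$\tau_{final,k}$, keeps the component nearest the centerline and reports
its area (sample count × spacing²) in mm², with stations as cumulative
arclength in mm via the voxel length in µm. The in-plane sample spacing
defaults to half the fit's spacing: counting a thresholded disc at 1-voxel
spacing fluctuates by about ±2 % per station, which would consume most of
the 5 % accuracy budget the phantom suite demands; halving the spacing
brings quantization below 1 % for radii ≥ 8 voxels. Empty slices become
gaps, never errors.

`align_profiles()` recovers the station offset between two profiles of the
same vessel (two preparation states) by normalized cross-correlation with
parabolic sub-station refinement. Two details matter on real profiles:
correlation operates on *high-pass detrended log-areas* — the log turns a
multiplicative area change into an additive one, and subtracting a running
mean (window = a quarter of the shorter profile) removes piecewise-constant
shrinkage structure that otherwise swamps the landmark features carrying
the alignment information — and candidate shifts must overlap at least
half of the shorter profile, because a short overlap containing a single
landmark correlates spuriously well. A known offset can always be passed
explicitly.

`shrinkage_profile()` interpolates the aligned follow-up profile onto the
baseline stations and reports $100\,(1 - A_{after}/A_{before})$ percent;
positive values mean area loss. Gaps and zero baseline areas propagate as
gaps.

## Segmentation preprocessing

The grayscale chain mirrors standard practice for artery tomograms:
`median_smooth()` (cubic neighborhood, default edge 15 voxels, borders
replicated), `region_grow()` (26-connected region within a fixed intensity
tolerance of the seed mean — the exposed, simplest criterion consistent
with interactive region-growing tools), and `morph_open()` (erosion then
dilation with a discrete Euclidean ball, computed exactly via squared
distance transforms; radius 20 is the cleanup used for debris-contaminated
lumina, radius 0 the identity). On a soft-edged circular lumen the
kernel-15 median relocates the half-maximum boundary by at most one voxel;
the direction follows the boundary curvature (at realistic
lumen-radius-to-kernel ratios the shift is a sub-voxel edge effect).
"Kernel size 15" is interpreted as the neighborhood edge and "eroded/
dilated by 20 voxels" as the ball radius; both are plain arguments, so the
other reading is one call away.

## Two-modality histogram analysis

`joint_histogram()` bins voxel-wise intensity pairs of two pre-registered
volumes (default 256 bins per axis over the 1st–99th percentile range,
out-of-range values clamped into the edge bins so counts are conserved and
marginals are exact row/column sums). `fit_multi_gaussian()` fits a sum of
Gaussians to histogram counts by Levenberg–Marquardt with positivity
bounds — a curve fit to peaks, deliberately not an EM mixture over latent
labels, because the peaks are the objects of interest. Initialization
takes the highest well-separated local maxima. For fitting, the full
intensity range (`probs = c(0, 1)`) is preferable: percentile clamping
concentrates the tails into the edge bins and those spikes attract
components.

`gaussian_prefilter()` (separable convolution, default $\sigma = 2$)
emulates the denoising that makes four tissue peaks (embedding paraffin,
fibrous tissue, vessel wall, residual plaque) separable in a noisy
modality. On the slab phantom it reduces within-class variance by ≈ 350×
and takes the histogram from one broad merged hump (one *prominent* peak —
`find_peaks()` uses topographic prominence precisely so that counting
noise undulations on the hump does not masquerade as separability) to four
sharp peaks whose fitted means land within a quarter bin of the class
means. One caveat is worth stating plainly: on an ideal sharp-class
phantom the *unfiltered* marginal is an exact four-Gaussian mixture, so a
four-component fit already sits at the counting-noise floor, and filtering
— which blurs class interfaces into partial-volume intensities — cannot
reduce the fit residual. What filtering restores is identifiability
(separable peaks, recoverable parameters), and that is what the tests
assert; on real tomograms the unfiltered histogram is additionally
distorted, which is why the filtered fit can also look better there.

## The phantom generator

Phantoms are unions of capsules: a voxel is foreground iff its center lies
within the locally interpolated radius of the (densely sampled) center
curve. Rasterization is exact for the continuous curve — an earlier
sphere-stamping implementation made boundary voxels flicker with the
sampling phase along the tube — and an exhaustive center-in-capsule oracle
reproduces the generator bit for bit in the tests. The ground-truth table
reports the curve, radii, arclengths, the nominal area $\pi r(t)^2$ *and*
the exact orthogonal section of the canal surface,
$\pi \max_j (r_j^2 - (s_j - s_i)^2)$: where the radius profile has a steep
arclength gradient $r'$, the canal section exceeds the nominal circle by
$\approx 1/(1 - r'^2)$, up to ~15 % on the benchmark's swelling flanks, and
it is the canal section that a correct pipeline must reproduce.

The built-in study conditions (`phantom_preset()`):

* `straight` — axis-aligned cylinder, r = 10, length 80: must converge at
  the first residual check with the axis recovered to machine precision.
* `bent` — circular arc, 20° overall direction change over ~200 voxels of
  length, r = 8, clipped at the stack faces like a vessel crossing the
  volume.
* `swelling-benchmark` — the bent tube with two Gaussian swellings to
  r = 14 and a constriction to r = 5: a thin geometry with local swellings
  and a plaque-like stenosis.
* `bifurcation` — the bent tube plus a blind-ended appendage standing in
  for a side branch: radius 2 (a quarter of the parent, as for a small
  side branch), length 90, leaving at 45°. The thin-long shape is a
  deliberate design point: the transient centroid bulge scales with branch
  volume times offset (so length buys bulge), while the *persistent*
  contamination — slices near the attachment where the branch wedge is
  still 8-connected to the lumen — scales with the branch radius squared.
  At radius 2 the converged centerline returns to within one voxel of the
  parent curve everywhere while an intermediate iterate still bulges by
  more than two voxels, and the branched fit needs strictly more
  iterations than the branchless control, the qualitative signature of
  bifurcation handling.
* `make_oblique_cylinder()` — a straight tube tilted in the x–z plane,
  with the axis extended past the z faces so every interior z plane cuts a
  complete ellipse; its orthogonal area is angle-independent, which is the
  discriminating test between per-z counting and orthogonal profiling.
* `make_shrinkage_pair()` — the same straight vessel in two preparation
  states: a dominant plaque-like constriction (the alignment landmark, as
  the real workflow aligns on the plaque) plus a minor swelling, and three
  segments whose areas are scaled by 0.85 / 0.65 / 0.35 with 10-voxel
  ramps, the follow-up volume cropped by 0.5 mm (at 10 µm voxels). The
  recovered offset and the 15/35/65 % segment medians — evaluated on flat
  windows away from landmarks and ramps, whose coordinates ship with the
  object — are the quantitative targets. Residual error (~±2.5 points) is
  dominated by lattice rasterization of r ≈ 10 discs and shrinks with
  radius.
* `make_two_modality_phantom()` — four-class label maps rendered with
  class-wise Gaussian intensities per modality, optionally with voxel-wise
  correlated noise (`noise_correlation = 1` gives the diagonal joint
  histogram of two identical acquisitions). Slab class maps keep the
  partial-volume fraction low while providing the four peaks.

What the phantoms deliberately do not emulate: reconstruction artefacts
(streaks, rings, phase wrapping), gas bubbles, intensity gradients across
the field of view, anisotropic deformation between states, and real
partial-volume profiles at tissue interfaces. Passing the suite therefore
demonstrates the geometry and the estimator are correct, not that
segmentation of a damaged, artefact-laden vessel is automatic — on real
data the preprocessing tolerances and seeds remain the analyst's job.

## Problem sizes and determinism

The test and reproduction suites run tubes of 80–300 slices in grids up to
112 × 48 × 197 and histogram phantoms up to 64 × 64 × 256 (≈ 10⁶ voxels);
these sizes keep every stage's behavior measurable (radii ≥ 8 voxels,
where rasterization error is below the 5 % tolerances) while a full run of
tests plus reproduction script stays within a few minutes on one core.
Everything outside `make_two_modality_phantom()` is deterministic;
the phantom takes an explicit seed, and `run_pipeline()` fixes the seed
from its config so repeated runs are byte-identical.

## Known limitations

* The centerline is single-branch by construction: a bifurcation is
  handled as a disturbance to be suppressed, not a second vessel to be
  traced.
* Slices orthogonal to a strongly curved centerline can cut the lumen
  twice; the nearest-component rule resolves this locally but very tight
  bends (curvature radius approaching the lumen radius) are out of scope.
* Within one slice half-extent of the stack faces, areas and centers rest
  on the replicated-face continuation model.
* The region-growing criterion is a fixed tolerance around the seed mean;
  adaptive or gradient-based criteria are not implemented.
* Alignment assumes a rigid station shift between profiles; non-uniform
  longitudinal distortion between preparation states is precisely what the
  shrinkage profile is meant to *measure*, so it must not be absorbed into
  the alignment.
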