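---
title: "Quantifying cell-driven matrix remodeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-driven matrix remodeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(remodelkit.verbose = FALSE)
library(remodelkit)
```

# Scope

Cells embedded in fibrous collagen (or collagen--Matrigel) hydrogels pull on,
compact, align and proteolytically degrade the surrounding matrix while they
migrate. `remodelkit` implements the image-quantification side of that
biology: given multi-channel confocal images (fiber channel, cell channel,
degradation reporter, vinculin), it measures

* the **microstructure** of the fiber network -- mean fiber length,
  persistence length and pore size;
* **fiber alignment** as a Fourier-domain anisotropy index and
  **densification** as the fiber-pixel fraction in control, alignment and
  peri-cellular band regions;
* **proteolytic degradation** as the volume of segmented dye-quenched (DQ)
  collagen signal per cell;
* **focal adhesions** (counts and sizes) in 2D immunofluorescence and 3D
  stacks of vinculin;
* **motility** from 2D time-lapse: mean accumulated distance (MAD) and
  migration speed.

Because the original microscopy data behind such studies is rarely deposited,
the package ships a synthetic-scene generator with exact ground truth, and
every pipeline is validated end-to-end against it.

# Containers and conventions

Images live in an `image_stack`: a `[y, x, z]` array plus a physical voxel
pitch `(dx, dy, dz)` in micrometres. Voxel `(i, j, k)` (1-based array
indices) is centred at `((j-1)*dx, (i-1)*dy, (k-1)*dz)` um; all reported
positions, lengths, areas and volumes are physical except where a published
parameter is defined in pixels (the 2D focal-adhesion size filter), in which
case the pixel value is primary and a um^2 column is provided alongside.
Confocal stacks are strongly anisotropic (e.g. 0.099 x 0.099 x 0.42 um or
0.312 x 0.312 x 0.49 um per voxel); every distance-based operation (pore
size, band ROIs, morphological closing, the 3D watershed) therefore runs on
an exact anisotropic Euclidean distance transform rather than voxel-count
approximations.

# Fiber morphometry

`binarize_fibers()` applies a Gaussian prefilter and windowed Otsu
thresholds (default window 65 px, roughly 6.4 um at 0.099 um/px -- wide
enough to straddle several pores). Windows whose intensity range falls below
a noise floor are classed as background; the floor is estimated as a
multiple (default 2) of the noise MAD computed from first differences of the
slice, which, unlike the raw-intensity MAD, does not grow with fiber
coverage.

`trace_fibers()` reconstructs fiber polylines from the mask: Zhang-Suen
thinning, decomposition of the skeleton adjacency graph into branches
between endpoints and junctions, and assembly of branches into fibers by
angle continuity -- at each junction the fiber continues along the unused
branch with the smallest turning angle, provided it stays below
`max_turn_deg` (default 40 degrees). Fiber extraction algorithms of the
nucleation-and-growth family measure the same polyline geometry; skeleton
tracing reproduces that geometry with far less machinery, and all downstream
metrics depend only on the polylines. Two details matter in practice:

* **Junction consolidation.** An oblique crossing of two fibers rasterizes
  into *two* junction clusters joined by a pixel-scale bridge. Bridges up to
  `junction_merge_px` (default 4 px) are absorbed into a single junction
  node, so angle continuity sees the true four-arm crossing. Without this, a
  30-degree crossing cannot be resolved at any turning threshold.
* **Pixel bookkeeping.** Branch pixels belong to exactly one fiber (or are
  discarded with fibers shorter than `min_fiber_um`); junction pixels are
  shared. The test suite asserts this partition explicitly.

`persistence_length()` pools tangent-angle correlations over all fibers and
fits the worm-like-chain decay `<cos(delta theta)>(s) = exp(-s/(2 Lp))` (2D
convention; `exp(-s/Lp)` for 3D geometry) by least squares on the
log-correlation, using arc separations up to half the mean fiber length.
Perfectly straight fibers have a non-decaying correlation and return `Inf`
rather than a spurious estimate. For the synthetic generator the true value
is known in closed form: a per-step von Mises turn with concentration
`kappa` gives a per-step correlation `I1(kappa)/I0(kappa)`, hence
`Lp = -step / (2 log(I1/I0))`; recovery at 500 fibers is within a few
percent.

`pore_size()` uses the "largest inscribed sphere" family: the Euclidean
distance transform of the background with fibers as obstacles, pore radii
read at the *regional maxima* of that field, and pore size defined as twice
their median. Regional maxima are computed plateau-correctly via
eps-reconstruction (a flat ridge hanging off higher structure is not a
maximum; a naive per-voxel test would call it one). On slab geometry --
parallel fiber planes a distance S apart with thickness t -- this definition
returns S - t exactly, which the tests pin.

Tracing operates on 2D masks; 3D stacks are binarized slice-wise and traced
on the maximum-intensity projection of the mask. This keeps the fiber
metrics well-defined on anisotropic stacks at the cost of foreshortening
steeply inclined fibers; pore size, by contrast, is computed fully in 3D.

# Anisotropy and densification

`anisotropy_index()` implements the Fourier orientation-tensor reduction:
mean-subtract, Hann window, power spectrum, restrict to a radial band
(default `4/side` to 0.45 cycles/px, excluding DC, illumination gradients
and the Nyquist corner), then form the second-moment orientation tensor of
spectral power over angle. The index is the eigenvalue contrast
`alpha = (l1 - l2)/(l1 + l2)`: the published method fixes only the
endpoints (0 for an isotropic network, 1 for a fully aligned one), and this
estimator satisfies both, is rotation-equivariant, and is the standard
tensor reduction of spectral orientation analysis. The dominant real-space
orientation is the leading eigenvector rotated by 90 degrees, since spectral
power lies perpendicular to the stripes that generate it. A featureless
patch returns `alpha = 0` by convention. On synthetic fields, `alpha`
increases monotonically in the generator's orientation concentration
(Spearman rho = 1 across kappa in {0, 0.5, 1, 2, 4, 16} in the tests), and a
sinusoidal grating scores above 0.999.

Whether anisotropy on a 3D stack should be computed per-slice or on a
maximum-intensity projection is not fixed by the published description; the
package computes it on whatever 2D patch it is handed and leaves the
reduction to the caller.

`moments_threshold()` is the Tsai moment-preserving threshold: the two
representative levels and the background fraction `p0` solve the
moment-preserving equations in closed form, and the threshold is the
smallest gray level at which the cumulative histogram reaches `p0`. The
returned solution satisfies the three moment equations to machine precision
(asserted at 1e-6), and the chosen cut agrees with an exhaustive 256-level
search up to the one-level quantization of `p0`.

`make_band_roi()` builds the peri-cellular "doughnut": all background
voxels within a physical distance (default 7 um) of the cell mask,
implemented on the anisotropic distance transform, i.e. a disc in 2D and a
spacing-corrected ellipsoid in 3D. A thickness below one voxel clamps to a
1-voxel rim. `fiber_density()` binarizes the *whole image once* with the
moments threshold and reports the fiber-pixel fraction per ROI; a single
global threshold keeps control, alignment and band densities comparable.
ROI placement is user-supplied or automated (`place_rois()`): the control
window minimizes overlap with dilated cell masks, the alignment window
centres on the midpoint between the two nearest cell centroids.

# Degradation volumetry

`dq_segment()` fixes the order threshold -> closing -> median: Tsai moments
threshold on the full stack, morphological closing with a physically
isotropic ball (in-plane radius `closing_r_px`, z-radius scaled by `dx/dz`),
then a binary median filter. Closing and median radii are not published;
the defaults (2 px, 1 px) are the smallest scales that realize the stated
intent -- fill interior gaps, remove isolated noise voxels. A slice-wise 2D
mode (`per_slice = TRUE`) mirrors pipelines built from 2D tools.
`dq_volume()` multiplies the foreground voxel count by the voxel volume,
counts 26-connected components, and normalizes per cell; the cell count
comes from a cell-channel mask (`count_cells()`) or is given explicitly.
Measured volume is additive over disjoint scenes, scales correctly under
resampling, and is linear in true blob volume with fitted slope within 10%
of one on the generator.

# Focal adhesions

The **2D pipeline** is the published sequence with its published parameters
as defaults: median filter (radius 2), rolling-ball background subtraction
(the sliding-paraboloid intent realized as a morphological opening with a
50 px disc; no radius is published), CLAHE (block 19, 256 bins, slope 6),
exponential remap `v -> (exp(ln 256 * v) - 1)/255` (the named "EXP" step,
normalized to preserve [0,1]), linear stretch saturating 0.35% per tail,
Laplacian-of-Gaussian with sigma (5, 5) px (sign-flipped so bright blobs are
maxima), automatic threshold within the cell mask, 3x3 closing, and particle
analysis keeping areas of at least 50 px^2 and circularity `4*pi*A/P^2`
(clamped at 1) within 0--1.0 -- at the defaults the circularity filter is a
no-op, retained for configurability. The automatic threshold is iterative
intermeans (the conventional "default" method of the reference ecosystem),
with one guard: the cut must also clear `median + 8 MAD` of the in-mask
response, so a featureless image yields zero detections instead of a noise
partition.

Two properties of this pipeline are worth stating plainly. First, counts are
recovered reliably: on generated scenes with separation constraints the
count error is at most one up to 25 FAs per cell. Second, *sizes are
systematically broadened*: a sigma-5 LoG smooths a puncta whose half-maximum
footprint is 60--120 px^2 into a detected support 1.3--1.5x larger. The
tests therefore pin counts tightly and assert only bounded broadening
(0.8x--3x) for areas; per-FA area should be read as a relative, not
absolute, measure at these footprint sizes.

The **3D pipeline**: 3D median (1-voxel ball), per-slice rolling-ball
(10 px), gamma enhancement, fixed threshold, EDM watershed, perinuclear
exclusion. Design choices where the published description is ambiguous:

* **Gamma direction.** "Gamma 2.1" is applied as `v^(1/2.1)`, which
  brightens mid-tones and enhances the bright FA tail ahead of a fixed
  threshold selecting "hyperintense" voxels; `v^2.1` would dim everything
  but the very top and make a fixed threshold fragile.
* **Threshold.** The published value is a manual fixed threshold and is not
  printed. A user-supplied `threshold` is honoured exactly. The automatic
  default is the 99th percentile of the post-gamma stack with the same
  8-MAD noise floor as in 2D. Note the percentile default ties segmented
  volume to stack size (it marks a fixed voxel fraction); for volume
  accuracy a fixed threshold at the object's half-maximum isophote is the
  right tool -- on generator scenes that value is known analytically
  (`0.5^(1/2.1)` after normalization) and recovers total volume within 20%.
* **Watershed.** Touching FAs are split on the negated Euclidean distance
  map with h-maxima merging: maxima whose dynamic (EDM height, in um) is
  below `watershed_dynamic` do not seed separate objects. Seeds are the
  regional maxima of the h-maxima transform, computed plateau-correctly;
  voxels are then assigned by descending-distance label propagation. A
  dumbbell of two spheres splits at a dynamic below the neck depth and
  merges above it, which the tests pin on a hand-built scene.
* **Perinuclear exclusion.** Vinculin around the Golgi/reticulum is removed
  by deleting FAs whose centroid lies within a fixed band (default 5 um,
  anisotropic distance) of the nucleus mask; an empty nucleus mask disables
  the step.

# Motility

Frames are CLAHE-enhanced and segmented by the intermeans fixed point --
iterated thresholding at the midpoint of the two region means, the same
mean-intensity criterion that graph-cut cell segmenters optimize, without
the graph machinery; the measured quantities downstream are track
statistics, and on separated-cell scenes the two segmenters agree.
Centroids are background-subtracted centres of mass (weights
`v - threshold`, clipped at zero), which move continuously with sub-pixel
motion; binary centroids flicker with boundary-pixel inclusion and inflate
accumulated distances by several percent at 2 um steps.

`link_tracks()` is constrained mutual nearest-neighbour linking: a link
requires both detections to choose each other and to lie within
`max_disp_um` (default 30 um/frame, about twice the fastest per-frame step
implied by published speeds at 15-minute intervals). No gap closing, no
division handling: a lost cell ends its track and a reappearing cell starts
a new one. `motility_stats()` reports MAD (mean over tracks of summed
frame-to-frame path length) and mean speed (mean of per-track accumulated
distance over elapsed hours). Tracks must span at least 75% of the
acquisition by default -- the published inclusion rule is unstated, and
without a cutoff short fragments would dilute MAD; `min_track_frames = 1`
restores "all tracks". When every track spans the full acquisition the two
speed conventions (mean of per-track speeds vs MAD over total time)
coincide; the published per-condition tables satisfy speed = MAD / 12 h at
print precision in all six columns, which the acceptance suite recomputes.

# The synthetic generator

All ground truth is computed from generating geometry *before*
rasterization and noise.

* **Fiber fields**: persistent random walks; initial orientations axial von
  Mises around `theta0` with concentration `kappa_orient` (0 = isotropic;
  sampled on the doubled angle, since fibers are axial), per-step turns von
  Mises with `kappa_step`, step 0.5 um, contour lengths uniform 6--14 um,
  rasterized with a Gaussian cross-profile (half-width 1 px, truncated at
  4 px so the far field is exactly empty). Concentrations of 1e6 or more
  are treated as the point-mass limit, giving exactly parallel, exactly
  straight fibers for limit tests.
* **FA scenes**: an ellipse/ellipsoid cell with diffuse cytoplasmic signal
  (0.2) over background (0.05), a physical nucleus sphere, and Gaussian
  punctae (peak 1.0) whose half-maximum footprint matches the requested
  size. Placement enforces pairwise separation (footprint radii plus at
  least 3 px) so recovery tests have unambiguous expected counts; bounded
  retries, then error. Read noise sigma 0.08 gives SNR of about 10 for the
  FA peak over the cell body.
* **DQ scenes**: compact raster-filled clusters of an exact voxel count,
  pairwise separated by more than the closing diameter, so truth volume is
  exact arithmetic and components never merge.
* **Time-lapses**: default 49 frames at 15-minute intervals (a 12-hour
  acquisition), per-frame steps uniform 1--3 um (mean speed 8 um/h, inside
  the published 3--13 um/h range), discs of radius 4 px at 2.5 um/px
  rendered with area-sampled edges and a 1 px Gaussian PSF -- a band-limited
  image whose centre of mass tracks the true sub-pixel position -- plus
  reflection at the field borders (step lengths, and hence accumulated
  distance, are preserved). No two cells approach closer than four radii at
  any frame, guaranteeing unambiguous linking; the constraint is re-sampled
  up to a bounded number of attempts, then errors.

What the generator does **not** emulate: realistic confocal PSFs and their
z-elongation, photobleaching, cell shape change and protrusions, fiber
cross-linking structure, spatially varying background. Passing tests
demonstrate correct measurement of scenes with known structure under mild
noise -- they do not certify performance on real microscopy, where
segmentation error, not arithmetic, dominates.

# Numerical choices and problem sizes

Exact anisotropic EDT (separable lower-envelope algorithm) underlies pore
size, band ROIs, ball morphology and the watershed; it is tested against
brute force. Connected components use 8-connectivity in 2D and
26-connectivity in 3D. Grayscale reconstruction (for h-maxima and
plateau-correct regional maxima) iterates neighbourhood dilation under a
ceiling to a fixed point. Ties in track linking break by smaller distance,
then lower label; junction continuation ties break toward the smaller
turning angle. Degenerate inputs fail loudly (constant images for
thresholds, empty masks, all-foreground pore queries) or return defined
conventions (empty networks, alpha = 0 for featureless patches, count 0
for blank FA images).

Validation scenes are sized for routine re-running: fiber fields of
128--256 px, FA stacks up to 96 x 96 x 48 voxels, 20-frame time-lapses,
with seed counts of 10--20 where distributions are asserted. The same
checks hold at larger sizes; the persistence-length and anisotropy
estimators are the only ones whose accuracy depends materially on sample
count, and both are asserted at the 300--500-fiber scale.

# Known limitations

* Fiber tracing is 2D (projection-based for stacks); true 3D skeleton
  tracing is not implemented.
* Mean fiber length depends on junction merge decisions; a single near-tie
  flip (e.g. under image rotation, via thinning asymmetry) moves the mean
  while leaving total traced length and pore size stable. Compare networks
  by total length where robustness matters.
* 2D FA areas are broadened by the sigma-5 LoG (above); counts are the
  robust output.
* The automatic 3D FA threshold marks a fixed intensity quantile and should
  not be used for absolute volumetry; supply a fixed threshold.
* No gap closing in tracking: occlusions fragment tracks rather than risk
  identity swaps.
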