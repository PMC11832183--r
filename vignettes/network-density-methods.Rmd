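---
title: "Quantifying 3D network length density in cleared tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D network length density in cleared tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Whole-mount cleared tissue imaged by confocal or light-sheet microscopy
yields large 3D stacks in which sympathetic nerve fibers (e.g. tyrosine
hydroxylase labeled) and blood vessels (e.g. CD31 labeled) appear as
bright curvilinear networks over a diffuse tissue background. The
biologically meaningful quantity is not signal area but *network length
per tissue volume* — a density that is robust to labeling intensity and
comparable across samples and conditions. `netdens` computes it in five
stages:

1. **Trainable segmentation.** A random forest classifies every voxel as
   network or background using a multiscale filter bank. The user trains
   it on sparse scribbles from their own data, which transfers across
   datasets far better than any fixed threshold.
2. **3D skeletonization.** The binary mask is thinned to a one-voxel
   centerline by homotopic thinning.
3. **Length measurement.** The skeleton's voxel graph (26-adjacency) is
   measured edge by edge in physical units, honoring anisotropic voxel
   spacing.
4. **Lobe volume.** The tissue volume actually present in the stack is
   estimated from the union of all segmented channels by morphological
   closing and hole filling: sparse networks sketch the tissue envelope.
5. **Density.** Length over lobe volume, reported per stack or per tile
   (heatmaps), with unit conversion (default m/m³) applied only at
   output.

A synthetic-phantom generator with exactly known centerline length closes
the loop: every stage, and the pipeline end to end, is validated against
analytic ground truth.

# Segmentation model

The classifier is a probability random forest (100 trees by default,
fixed seed, single-threaded for reproducibility) over per-voxel features
computed at four smoothing scales, by default $\sigma \in \{1, 2, 4, 8\}
\times dx$ µm: Gaussian intensity, difference of Gaussians between
consecutive scales, gradient magnitude, Laplacian, and the three
eigenvalues of the Hessian (the standard curvilinear-structure cues:
for a bright tube, two strongly negative eigenvalues and one near zero).
All scales are physical (µm) and converted per axis to voxel units, so a
trained classifier transfers between stacks with different calibration.
Derivatives are central differences on the Gaussian-smoothed volume,
divided by the per-axis spacing.

Decision rule: a voxel is foreground when the posterior is at least 0.5,
ties included — deterministic and biased toward recall of thin
structures, which matters because a missed centerline voxel can
disconnect a fiber. For strongly anisotropic stacks (dz ≫ dx, e.g. 15 µm
z steps at 1.2 µm pixels) the bank can be switched to per-slice 2D
filtering (`use_3d = FALSE`); a 3D sigma smaller than half a voxel on
any active axis is rejected rather than silently aliased.

The "acceleration" toggle applies the trained forest in chunks; it is a
memory/throughput knob with a hard contract of numerically identical
masks, enforced by test.

A fixed-threshold comparator (`fixed_threshold_area`, strictly greater
than a gray value, 170 by default on 8-bit data) is included as the
baseline that trainable segmentation is measured against: on phantoms
where tube radius varies, thresholded area decorrelates from length
while the skeleton pipeline does not.

# Skeletonization and length

Thinning deletes *simple points* — voxels whose removal provably
preserves topology under the (26, 6) foreground/background connectivity
pair: the foreground of the voxel's 26-neighborhood must form one
26-component, and the background of its 18-neighborhood one 6-component
touching a face neighbor. Deletion proceeds in six directional
subiterations (alternating faces keeps erosion symmetric); within each
subiteration candidates are ordered by their anisotropic Euclidean
distance to the background, so deeper voxels survive and the final curve
sits on the medial line even when dz ≠ dx. Each deletion is re-validated
against the current state, which makes the sequential procedure
homotopy-safe regardless of ordering. Endpoints (≤ 1 foreground
neighbor) are never deleted. The result: connected components and cycles
are preserved exactly (a thinned solid torus keeps exactly one cycle),
and no 2×2×2 solid block survives.

Length is the sum over all unique pairs of 26-adjacent skeleton voxels
of the physical distance between their centers,
$\sqrt{(\Delta z\,dz)^2 + (\Delta y\,dy)^2 + (\Delta x\,dx)^2}$.
This definition is simple, exactly testable against a brute-force
oracle, and anisotropy-aware without resampling the volume (interpolating
a 15 µm-stepped stack would manufacture data). Its known bias: a digital
26-chain overestimates the length of an oblique smooth curve — up to
about 12% for unfavorable directions, growing with z-anisotropy — and
junction voxels contribute all incident edges, adding small cliques
where fibers cross. End caps of tubes extend the skeleton by roughly one
tube radius per end. Spur pruning is deliberately not offered: it would
silently change the measurement; the particle filter upstream is the
supported way to remove debris. The phantom suite bounds the aggregate
effect: per-stack recovery errors on the reference conditions average
about +10% and stay within ±15%.

# Particle exclusion

Antibody aggregates and debris segment as small, compact blobs. The
optional filter removes, per 2D z-slice, connected components with area
≤ `max_size` px² *and* circularity $4\pi A / P^2$ inside a configured
range. Circularity is a 2D measure, hence the per-slice convention. The
perimeter estimator is fixed to boundary-crack length (count of exposed
pixel edges) because circularity values are meaningless unless the
estimator is pinned: under the crack estimator a digital disc sits near
0.5–0.65 and a 1-pixel-wide line near 0.1, so a lower bound around 0.4
separates compact debris from fiber fragments. A single pixel is defined
to have circularity 1. The filter only removes (output ⊆ input), is
idempotent, and is disabled by default; the shipped default values
(max 50 px², range [0.5, 1]) are placeholders that users should tune on
their own data.

# Lobe volume and density

Tissue volume is estimated from the voxelwise union of all segmented
channels: morphological closing with a *physical* ball (radius in µm,
implemented via exact anisotropic Euclidean distance transforms, 50 µm
default) bridges the gaps between neighboring structures, then enclosed
cavities are filled (6-connected background components not reaching the
volume border). Because closing with a convex element can never escape
the convex hull of the true tissue region, the estimate approaches the
true envelope from below as structures sample it more densely; on
ellipsoid-envelope phantoms with a closing radius near the mean
inter-tube gap the recovered volume is within a few percent of the
analytic value, and it is monotone non-decreasing in the closing radius.

Density is computed in µm/µm³ internally and converted once, at output,
with exact powers of ten (m/m³ = µm/µm³ × 10¹²). A tile with zero or
near-zero lobe volume (< 1% of the tile extent by default) is reported
`NaN` ("outside the lobe"), never 0 — tissue absence and tissue without
network are different findings. For heatmaps the lobe mask is built on
the whole stack *before* tiling, so per-tile volumes are exactly
additive and closing cannot create seam artifacts; tiling the skeleton
loses only edges cut by tile borders (bounded by the cut count times
the maximal edge length, checked by test).

# The phantom generator

`phantom_spec()` defines the reference study conditions for validation:
a 40 × 160 × 160 voxel stack at (1.5, 1, 1) µm spacing containing
persistent-random-walk tubes (persistence 0.92, step 4 µm, 40 steps =
160 µm per tube, radius 2.5 µm by default), rasterized as all voxels
within the tube radius of the centerline (anisotropic distance), over a
background of 30 gray values with tube intensity 200, Gaussian PSF blur
of 0.8 µm and additive Gaussian noise (sd 10) on an 8-bit range. Ground
truth length is pure geometry — the polyline segment sum — exact to
machine precision and independent of rasterization. The validation set
mirrors the 2-training / 8-validation design, with tube count (2–9) and
radius (2–4 µm) varied deterministically across stacks so that true
lengths span roughly a factor of five.

Three generator behaviors are deliberate design choices rather than
incidental details:

* **Self- and mutual avoidance.** Steps that would bring a walk within
  $2r + 3\,\max(dz,dy,dx)$ of its own earlier path or of another tube
  are re-drawn (with progressively relaxed persistence so a cornered
  walk can actually turn). Biological fibers do not self-overlap; more
  importantly, a mask that merges with itself locally forms a plate,
  and a plate has a medial *surface*, not a curve — no curve skeleton
  of it measures its length meaningfully. The margin of three voxels
  over the diameter prevents rasterization from bridging near-parallel
  tubes intermittently.
* **Grazing boundary redirection.** At the grid or envelope boundary
  the direction is projected onto the wall's tangent plane with a small
  inward bias (turns ≤ ~90°). A mirror bounce at near-normal incidence
  would fold the tube back onto itself inside the avoidance exemption
  window — the same plate problem.
* **Moderate anisotropy (dz/dx = 1.5).** The instrument's own
  anisotropy in deep-tissue stacks is far larger (~12×), but tubes of
  2–4 µm radius are simply unresolvable at 15 µm steps, and 26-chain
  length bias grows with anisotropy. The phantom validates the method
  in the regime where the measurement is well posed; conclusions about
  heavily undersampled z do not follow from it. This is stated as a
  limitation, not hidden.

What the phantoms do *not* emulate: depth-dependent attenuation and
scattering, detector gain ramps, branching trees (bifurcation is off by
default because branching changes the skeleton-length bias),
non-Gaussian speckle, and anatomical correlation between neurons and
vessels. Passing the phantom suite therefore demonstrates correctness
of the measurement chain, not performance on any particular real
dataset — for real data the classifier must be retrained and the QC
montages inspected.

# Evaluation harness

`regress_paired` reports ordinary least squares of measured on
reference *with* intercept — the intercept is a bias diagnostic and is
never forced through zero — plus r² (squared Pearson correlation, which
for OLS with intercept coincides with the coefficient of
determination) and the mean absolute error in the input unit, with no
silent unit conversion. `annotator_spread` summarizes independent
measurements of one stack by absolute deviation from their mean. At the
reference phantom conditions the end-to-end pipeline (train on 2,
quantify 8) achieves r² above 0.99 with slope ≈ 1.09 and an intercept
below 2% of the mean true length; the slope above 1 is the documented
chain-length bias, which cancels in any comparison performed with the
same pipeline on both arms.

# Numerical and reproducibility choices

* All randomness (phantoms, annotation sampling, forest training) flows
  from explicit integer seeds; per-stack seeds derive deterministically
  from one global seed. Repeat runs of `run_pipeline` with the same
  config and seed produce byte-identical `results.csv`, acceleration on
  or off.
* Voxel spacing is supplied by the user (config/CLI), never parsed from
  TIFF tags — tag dialects are unreliable; a conflicting tag produces a
  warning and is ignored. The refractive-index z correction is a single
  positive scale factor on dz (default 1), applied before any
  measurement; composing factors multiplies them.
* Axis order is fixed at (z, y, x), channel-first for multi-channel
  stacks; 8- and 16-bit TIFF round-trips are voxel-exact.
* Distance transforms are exact (separable lower-envelope algorithm on
  squared distances with per-axis spacing); morphology therefore uses
  true physical balls, not voxel-count approximations.
* Degenerate inputs have defined behavior: empty masks skeletonize to
  empty skeletons of length 0; an empty mask union warns and yields
  lobe volume 0 with downstream tiles flagged; a constant reference in
  the regression is an error, not a NaN.
* Problem sizes in the shipped validation suite (reference phantom
  grid 40 × 160 × 160, 10-stack sets, a 3-stack determinism set at
  16 × 64 × 64) were chosen so the full suite and the acceptance script
  each complete in minutes on a single CPU while still exercising every
  stage at realistic sparsity (~1% tube volume fill, comparable to
  sparse innervation).

# Known limitations

* The 26-chain length definition overestimates oblique curve length;
  the bias is multiplicative (≈ +9% under reference conditions) and
  consistent, so *comparisons* are unaffected, but absolute lengths
  carry it. Branch-wise spline fitting would reduce it at the cost of
  a far less testable contract.
* Circularity depends on the perimeter estimator; values from other
  tools (polygonal or smoothed-boundary estimators) are not directly
  comparable to the crack-length convention used here.
* The lobe-volume construction assumes the labeled networks sample the
  tissue envelope densely relative to the closing radius; in nearly
  network-free tissue it underestimates volume (and flags tiles rather
  than inventing density).
* Per-slice 2D features discard z context; they are the right choice
  only when dz makes 3D filters degenerate.
* The classifier is a shallow learner on hand-crafted features: robust
  with minimal training data and cheap to run, but not competitive
  with deep segmentation given abundant ground truth.
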