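---
title: "Methods: closed-curve fibre segmentation, morphometry and edge-spread resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-curve fibre segmentation, morphometry and edge-spread resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervenano)
```

## The imaging situation

X-ray phase-contrast holographic nanotomography of osmium-stained peripheral
nerve produces isotropic reconstructions (on the order of 100–150 nm voxels,
2048³ grids, a ~266 µm field of view) in which myelin sheaths appear as dark
annuli around brighter axoplasm in the x–y slices, with fibres running
roughly along z. nervenano works on such volumes: it traces individual
myelinated fibres as stacked closed curves, extracts morphometry (equivalent
diameters, myelin thickness, g-ratio, fibre density, node-of-Ranvier gaps,
and a winding statistic for regenerative clusters), and estimates the
spatial resolution from grey-value edge transitions. Because clinical
volumes of this kind are ethically restricted, the package ships a phantom
generator that reproduces the geometry and image statistics the analysis
relies on, with full ground truth, and every stage is validated against it.

Intensities are treated as arbitrary units throughout; nothing assumes a
physical grey-value scale, only the ordering myelin < axoplasm < background.

## Per-slice segmentation model

One fibre in one slice is modelled as a pair of closed star-shaped curves
about a center: `n_angles` spokes at angles `2*pi*i/n_angles`, each carrying
a radius. The image is resampled onto this polar grid by bilinear
interpolation (`polar_unwrap()`), and edge evidence is the radial derivative
by central differences: the outer boundary (dark myelin to bright
background) scores `-dI/dr`, the inner boundary (bright axoplasm to dark
myelin) scores `+dI/dr`, so that lower cost means a stronger edge of the
correct polarity.

The curve is the global minimizer of

    sum_i cost(i, r_i) + lambda * sum_i (r_{i+1} - r_i)^2,
    |r_{i+1} - r_i| <= delta  for all i, including the wrap pair,

found by dynamic programming (`dp_circular_path()`). Exact closure of the
wrap pair matters — a single-pass DP that ignores the wrap can return an
open spiral — so the programme is run once per candidate start radius and
the best wrap-consistent path kept; with the default 72 angles and 60 radii
this exactness costs little (the kernel is compiled). Ties break toward the
smaller total radius, then the smaller start radius, which makes results
reproducible on degenerate cost grids. The implementation is checked in the
test suite against exhaustive enumeration of all wrap-consistent paths on
small grids.

`fit_contour()` runs the outer path first, restricted to a radial window
around the initial radius (0.45× to 1.6× + 2 voxels); the inner path is then
found strictly inside it. The center is moved to the area centroid
(shoelace) of the outer polygon and the fit repeated once — two fixed
passes, which recenters accurately without a convergence loop that could
oscillate on noisy slices.

### Myelin-gap (node) handling

In a node of Ranvier the sheath is absent, so there is no bright-to-dark
inner edge and the inner path is unconstrained by real structure. Rather
than trust it, each slice is tested for myelin presence directly: the mean
intensity of the band between the two paths must be darker than the
axoplasm core (the innermost 30% of the outer radius) by at least
`gap_contrast` (default 0.1 intensity units at the generator's default
contrast; exposed in `segmentation_params()`). Slices failing the test are
flagged as gaps, the inner path is placed touching the outer one, and
flagged slices are excluded from morphometry summaries.
`detect_myelin_gaps()` then reports maximal runs of at least
`min_gap_slices` thin slices as half-open z-intervals.

## Propagation along the fibre

`propagate()` fits the seed slice and marches in both z directions, each
slice initialized from the previous centroid and mean outer radius — the
formalization of the assumption that the surface moves only slightly
between slices. A direction ends when

* the mean outer-path cost exceeds `cost_threshold` (the fibre is lost),
* the recentred centroid jumps farther than `max_drift` (3 voxels),
* the contour would leave the slice, or the z range ends (volume edge),
* `max_slices` is reached.

`cost_threshold` is calibrated, not guessed: `calibrate_cost_threshold()`
fits contours in pure background-plus-noise slices and returns the 5th
percentile of the resulting mean costs, so that 95% of pure-noise fits are
flagged as lost while true myelin edges (which score an order of magnitude
lower) always pass. The shipped default (−0.021) is this calibration at the
generator's default noise (sigma 0.05); recalibrate for other noise levels.

Across a node gap the tracker remembers the last pre-gap outer calibre and
keeps the search window wide enough to recapture the sheath — including the
paranodal swelling — when it resumes after the gap; otherwise the window,
tied to the collapsed axon-only radius inside the gap, could not re-expand.

Seeding is deliberately manual (slice, center, radius per fibre): the
method is semi-automated, and automatic fibre detection is out of scope.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_angles` | 72 | – | angular resolution of the curve |
| `n_radii` | 60 | – | radial resolution of the search |
| `r_max_vox` | 45 | voxels | hard cap on the unwrap radius |
| `delta` | 1 | radial samples | max radial jump per angular step |
| `lambda` | 0.1 | voxel² | smoothness; converted to sample units per unwrap so behaviour is independent of fibre size |
| `max_drift` | 3 | voxels | per-slice center-motion bound |
| `cost_threshold` | −0.021 | intensity/sample | lost-fibre gate (noise-calibrated) |
| `gap_contrast` | 0.1 | intensity | myelin-presence margin |

The radial extent actually unwrapped is `min(r_max_vox, 1.6*r_init + 2)`,
so the radial step adapts to the fibre; `lambda` is specified in voxel²
precisely so that this adaptation does not change the effective smoothness
(an early sample-unit version over-smoothed small fibres and failed to
recenter on them).

## Morphometry

Areas come from the shoelace formula on the contour polygons; equivalent
diameter is `2*sqrt(area/pi)`; myelin thickness is the mean over angles of
(outer − inner) radius; the g-ratio is the ratio of equivalent axon to
fibre diameter, which is robust to non-circular contours because the
polygon factor cancels. Contours are star-shaped by construction and cannot
self-intersect. Fibre density counts centerline points inside a rectangular
ROI per mm²; the "large fibre" filter defaults to an equivalent diameter of
at least 6 µm, a documented placeholder in the absence of an established
cut-off.

The intertwining statistic for regenerative clusters is a winding number:
on the shared z grid of two centerlines, the in-plane vector from one to
the other is tracked, its polar-angle increments are unwrapped to
(−π, π], and their sum divided by 2π is the signed number of turns. It is
symmetric in the pair, flips sign under z reversal, and is invariant under
global in-plane rotation — all asserted in tests. A pair is flagged
intertwined at |turns| ≥ 0.5 by default; the observation the statistic
formalizes is binary (twisted clusters vs parallel fibres and
non-interacting neighbouring clusters), and half a revolution cleanly
separates the two regimes at desk scale. The threshold is exposed.

## Edge-spread resolution

A probe line across a material edge yields a profile fitted by least
squares with `I(x) = a + b*tanh((x - x0)/w)` (Levenberg–Marquardt via
minpack.lm; initialization from end-quartile means, the maximum finite
difference, and twice the sample spacing; relative tolerance 1e-8, 200
iterations). The resolution estimate is the FWHM of the model's analytic
derivative: `sech²` reaches half its maximum at `cosh(u) = sqrt(2)`, so
FWHM = `2*ln(1+sqrt(2))*w ≈ 1.762747*w`. `estimate_resolution()` runs many
probes (12 by default, mirroring common practice), rejects non-converged
fits and fits with RMS residual above 0.15|b|, and reports the mean, sd and
count of the accepted FWHMs. Probes are 1D lines (not averaged strips), 20
samples at one-voxel spacing by default, drawn radially across segmented
outer boundaries in auto mode so that they cross the highest-contrast edge
perpendicularly.

Two numerical caveats are documented because they are easy to trip over.
First, the tanh family is not the Gaussian edge family: the best-fit tanh
width to a Gaussian-blurred step depends on how much flat tail the fit
window includes (the FWHM ratio to `2.3548*sigma` is ≈0.98 at ±2σ, ≈0.93 at
±3σ, ≈0.90 for very wide windows). The package's validation fits the
transition region (±3σ), standard practice for edge-spread analysis; on
probes much longer than the blur the reported FWHM will sit a few percent
below the Gaussian value. Second, rasterized phantom edges carry an extra
~1-voxel box smoothing from anti-aliasing, which adds ~6% to the measured
width at the default psf of 0.8 voxels; both effects fit comfortably inside
the validation tolerances.

## The phantom generator

`simulate_study_volume()` renders, at 130 nm voxels on a 128×256×256 grid
by default:

* ten large wavy parallel fibres — sinusoidal in-plane waveform (0.8 µm
  amplitude, 33 µm period), outer radii drawn from 2.0–3.5 µm diameter
  equivalents (outer radius 1.6–2.6 µm), g-ratio 0.55–0.70;
* two regenerative clusters of three thin fibres (outer radius 0.9–1.2 µm)
  helically twisted about a shared axis (1.8 µm helix radius, 2 turns over
  the stack), clusters separated by a configured clearance — so
  within-cluster pairs wind about each other and cross-cluster pairs do
  not;
* optionally a node of Ranvier (8-slice myelin gap with ×1.5 paranodal
  swelling over 5 flanking slices), a bulb-terminated degenerated stump
  ("dead end") next to one paranode, a thin sprout diverging from the other
  paranode, and Schmidt-Lanterman-like incisures modelled as 40% myelin
  thinning;
* one solid low-contrast vessel;
* intensity ordering myelin (0.15) < axoplasm (0.55) < vessel (0.8) <
  background (1.0), anti-aliased by 2× supersampling, then isotropic
  Gaussian blur (sigma 0.8 voxels) and additive Gaussian noise (sigma
  0.05).

Geometry choices are order-of-magnitude plausible for human peripheral
nerve at this voxel size and were fixed once, subject to one hard
constraint: ten non-overlapping wavy fibres plus two clusters and a vessel
must actually fit in the 33 µm cross-section, which bounds the large-fibre
calibre well below the largest fibres seen in vivo. The phantom is
deterministic given its seed; placement is rejection sampling with a
per-object margin, and overlaps at render time are resolved by draw order
(later overwrites earlier).

What the phantom does **not** emulate: reconstruction artifacts (rings,
streaks, phase-retrieval residuals), intensity inhomogeneity, Schwann-cell
nuclei and organelles, unmyelinated axons, connective tissue texture, and
truly eccentric or non-circular sheaths. Passing the phantom-based tests
therefore demonstrates correctness of the geometry and estimators under the
stated image model, not robustness to every artifact of real acquisitions;
on real volumes the manual-seeded, threshold-gated design still expects
occasional operator corrections.

## Problem sizes and determinism

The validation suite runs the full default phantom (128×256×256, all ten
large fibres traced over all 128 slices) for parameter recovery, a
40×128×128 single-fibre phantom for the 12-probe resolution experiment, and
small (4–32 slice) phantoms for property tests; these sizes were chosen so
the complete suite exercises every stage end-to-end at full fidelity while
remaining convenient to run routinely. All randomness flows through
explicit seeds (`phantom_config(seed=)`, `degrade(seed=)`, probe placement
seeds), and the RNG state of the calling session is always restored.

## Known limitations

* TIFF output is restricted to intensities in [0, 1] and quantized at
  2⁻³² (the TIFF backend stores scaled 32-bit integers); the raw +
  YAML-sidecar format is the lossless interchange route. HDF5 I/O is not
  provided in this build.
* Voxel-level labels at object boundaries follow a majority rule and carry
  a half-voxel perimeter bias — visible as a few percent on the area of
  small discs, immaterial for the annulus statistics the tests rely on.
* The tracker is single-fibre and seed-driven; it does not detect fibres,
  segment vessels (deliberately — their contrast regime is different), or
  handle fibres that merge or branch within a slice.
* Sub-voxel radial refinement (parabolic, `subvoxel = TRUE`) is off by
  default; the default radial sampling already recovers radii to well under
  half a voxel on the phantom.
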