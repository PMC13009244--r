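---
title: "Methods: correlative transcript-collagen spatial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlative transcript-collagen spatial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`corrmap` quantifies the spatial relationship between chromogenic
in-situ-hybridization transcript dots (brightfield RGB) and collagen fiber
architecture (second-harmonic-generation, SHG) in one tissue section. This
vignette explains the procedure, its assumptions, the parameters that
matter, and the design decisions taken where the problem left room.

## Coordinate and unit conventions

All tables use (row, col) pixel coordinates, 0-based, with pixel centers at
integer coordinates. All downstream analysis runs in the SHG frame at
0.63 µm/px — the native resolution of the SHG acquisition — so the
proximity radii of 10–100 px convert to 6.3–63 µm. `px_to_um()` /
`um_to_px()` perform these conversions.

## Dot detection

Chromogenic dots are reddish: their green share is low relative to red and
blue. The detector computes the pixelwise chromatic ratio
`G / (R + B + ε)` with ε = 0.001 guarding the denominator, classifies
pixels with ratio < 0.4 as candidates, labels connected components
(8-connectivity by default), and keeps components of at least
`min_area_px = 2` pixels. Centroids are unweighted means of component
pixel coordinates; areas are pixel counts.

Two guards reflect properties of the ratio rule rather than of the tissue:

* perfectly black pixels have ratio 0 and would classify as dots, so
  detection is restricted to the tissue mask;
* the minimum-area filter removes isolated dark specks.

No circularity filter is applied by default — the detection rule is purely
chromatic — but an eccentricity cutoff is exposed
(`dot_params(max_eccentricity =)`) for data where it helps.

The tissue mask itself (needed for the per-mm² normalization and for the
null model's support) is computed as luminance below an Otsu threshold,
followed by morphological closing (disc radius 5 px) and hole filling.
This is a pragmatic stand-in: nothing in the dot-detection rule depends on
how the mask is obtained, and a hand-drawn mask can be passed instead.

## SHG preprocessing and fiber morphometrics

The SHG image is normalized to [0, 1], gamma-corrected with γ = 0.75,
median-filtered with a 2×2 window, and rescaled. A 2×2 window has no
center pixel: the window anchored at (r, c) spans offsets {−1, 0} per axis
and the median of four values is the mean of the two middle order
statistics, the usual rank-filter convention for even windows.

Segmentation is a pluggable backend mapping the preprocessed image to a
binary skeleton, so a learned segmenter can replace the default without
touching anything downstream. Two backends ship:

* `"sauvola"` (default): Sauvola adaptive threshold (window 15, k = 0.2,
  integral-image implementation) intersected with a global Otsu floor —
  the floor prevents noise-only background regions, where any local
  threshold must pass some pixels, from contributing spurious segments —
  followed by Zhang–Suen thinning;
* `"identity"`: treats bright pixels as an already-1-px-wide skeleton.
  This is the bridge to the generator's exact ground truth and the hook
  for precomputed segmentations.

The skeleton is split into junction-free branches: junction pixels are
those with crossing number ≥ 3 (the count of 0→1 transitions around the
8-neighborhood). Neighbor count alone misclassifies ordinary staircase
corners of a thinned skeleton as junctions and fragments fibers — the
crossing number does not. Because removing a junction pixel alone can
leave its branch stubs diagonally connected around the hole, the
junction's whole 8-neighborhood is excised; each branch loses at most one
pixel per junction end. Terminal spurs shorter than 3 px are pruned first
(thick-skeleton artifacts), and branches shorter than 3 px are dropped —
1–2 px fragments carry no orientation or tortuosity information. One
branch = one fiber with a unique id; whether a connected skeleton should
instead count as a single fiber is genuinely open, and the branch-level
definition was chosen because it is reproducible and segmentation-backend
agnostic.

Per-fiber metrics, computed on the ordered branch path:

* **length**: sum of step weights along the path — axial steps 1, diagonal
  steps √2 — times 0.63 µm;
* **orientation**: angle of the endpoint-to-endpoint vector, measured from
  the column axis and folded into the half-open interval [0, π). The
  half-open choice avoids double-counting the horizontal direction (π ≡ 0)
  when averaging axial angles;
* **tortuosity**: path length over Euclidean endpoint distance, ≥ 1, with
  equality for collinear paths. Closed loops (identical endpoints) have
  undefined tortuosity and are flagged, not forced to a value; their
  orientation falls back to the principal axis of the path pixels, also
  flagged.

Property maps place each fiber's value on its skeleton pixels (NA
elsewhere); they are the substrate for grid aggregation.

## Registration

The brightfield (moving) image is aligned to the SHG (fixed) frame with a
rigid transform — same slide imaged twice, minimal deformation — escalating
to affine on request. The transform maps moving coordinates *into* the
fixed frame; point warping is an exact coordinate mapping with no
resampling, so measuring proximity after warping dots equals warping first
and measuring, by construction.

The optimizer is deterministic: an exhaustive coarse search over rotation
(default ±12° in 1.5° steps at a downsampled level, translation per angle
by FFT cross-correlation) followed by Nelder–Mead refinement at increasing
resolution, using every overlapping pixel — no random metric sampling, no
seed. The default similarity metric is normalized cross-correlation, which
is appropriate when the two images are monotonically related; a
joint-histogram mutual-information metric (32 bins) is available via
`options = list(metric = "mi")` for genuinely cross-modal pairs. Differing
acquisition magnifications are handled by an initial isotropic scale
(`init_scale`), e.g. the ratio of stated pixel sizes.

On synthetic rigid misalignments up to ±20 px and ±10°, recovery errors
are of order 0.01 px and 0.01° — far inside the 1 px / 0.5° contract the
tests assert.

## Macroscale grid

The SHG frame is tiled with 100×100 px cells (partial edge cells kept and
flagged). Cell feature means are **pixel-weighted** — the mean of
property-map pixels in the cell — because the per-pixel maps are the
defined intermediate; a per-fiber mode would weight each fiber once
regardless of how much of it crosses the cell, and which the original
analysis used is unknowable from the outside. Orientation is averaged with
the axial circular mean (angles doubled, vector-averaged, halved) because
the arithmetic mean is meaningless across the 0/π wrap. Cells without
skeleton pixels have undefined feature means (never zero-filled); dot
counts are defined everywhere, with boundary centroids assigned by the
half-open cell convention. The feature-vs-feature Spearman matrix uses
mid-ranks and pairwise-complete cells; entries with fewer than 3 valid
pairs or zero rank variance are flagged NA rather than imputed. p-values
are not computed.

## Proximity analysis and the null model

For every dot and radius r ∈ {10, ..., 100} px, a fiber is *included* if
any of its skeleton pixels lies within r of the dot centroid — in the
circle partially or fully. Per dot, included fibers contribute once,
unweighted, to feature means; weighting by the skeleton-pixel count inside
the circle is a defensible alternative, but unweighted contribution keeps
"the fibers near this dot" the statistical unit. Dots with no fiber in the
circle are *excluded* from feature means at that radius and reported in
the isolated fraction instead — averaging zeros in would fabricate decay.
Dot-level means are averaged across dots with SEM = sd/√n; the dot within
one sample is the unit of aggregation, and nothing is pooled across
samples.

Profiles are normalized to the value at the smallest radius (where the
decaying length profile peaks) and summarized by an ordinary least-squares
slope against radius in µm — "slope" is not otherwise defined in this kind
of comparison, and OLS over all radii is the least surprising choice.

The null model redraws dot locations uniformly **from the tissue-mask
pixels** (seeded, default n = 5000) and recomputes the full profile.
Constraining the null to the mask matters: uniform placement over the full
frame would park pseudo-dots on empty background and trivially inflate
isolation; the tissue support is the meaningful null. The distance engine
buckets skeleton pixels into cells of the maximum radius so each pseudo-dot
only visits 9 cells; the result is contractually identical to brute-force
all-pairs distances, and the test suite asserts exactly that.

## The synthetic generator

Fibers are smooth biased-angle random walks: unit steps with Gaussian
heading increments, rounded to a pixel chain that is kept *simple* (each
pixel 8-adjacent only to its predecessor and successor) and separated from
other fibers by a Chebyshev clearance of 2 px, so rendered scenes
re-trace exactly. The heading dispersion for a target tortuosity comes
from the worm-like-chain end-to-end relation; the recorded ground truth is
always the realized path value, never the target. Lengths are drawn from
8–45 µm by default, spanning short fibers of normal muscle to the long
fibers of fibrotic tissue; base orientations are uniform on [0, π).
Rendered skeletons are dilated to 2 px width (1 px for exactness
experiments) at intensity 180 over a background of 10 with Gaussian noise
(sd 8), clipped to 0–255.

Dots are non-overlapping discs (radius 2–4 px, ≥3 px clearance) whose
centers sit on tissue-mask pixels; disc pixels are drawn from a reddish
color model (R 100–160, G 10–40, B 20–60) that always satisfies
ratio < 0.4, and background pixels from a hematoxylin-like model
(R 150–200, G 130–180, B 170–220) with G raised to the minimal compliant
value wherever the raw draw would fall below ratio 0.4 — the plain ranges
alone do not guarantee separation, and the clamp is what makes the
generator a valid oracle for the detector. The optional enrichment rule
places dot centers within a set radius (15 px in the coupled experiments)
of skeleton pixels of fibers in the top length quantile (0.6), creating
the long-fibers-near-dots coupling the null model is meant to detect.

What the generator does **not** emulate: out-of-focus blur, chromatic
aberration and staining variability of real brightfield scans; SHG speckle,
depth attenuation and fiber-crossing intensity profiles; dots overlapping
each other or lying on fibers' pixels. Passing tests therefore demonstrate
the correctness of the algorithms under their stated contracts, not
segmentation accuracy on real tissue — the segmentation backend remains
the pluggable, data-dependent component.

## Numerical choices and degenerate inputs

* Metric exactness: generator path metrics and re-traced metrics agree to
  1e-9 relative tolerance (in practice exactly).
* Tortuosity is reported when ≥ 1 − 1e−12; closed loops are NA + flag.
* Empty inputs: a blank SHG image yields an empty fiber table (not an
  error); an empty dot table makes the proximity profile an error (there
  is nothing to center on) while an empty fiber table yields an
  all-isolated profile; a zero-area tissue mask makes densities an error.
* Placement failures in the generator (scene too crowded) raise explicit
  errors after bounded retries.
* Pipeline CSVs format numerics with 9 significant digits so identical
  runs are byte-identical.

## Test problem sizes

The suite and the acceptance script run on scenes of 200–300 px per side
with 25–60 fibers and 25–50 dots, 300–500 randomized null locations, and
20-replicate calibration/coupling experiments; the metric-exactness check
accumulates ≥ 1000 generated paths. These sizes give stable statistics
(calibration p-values well away from the 0.05 boundary, coupling detected
in 20/20 replicates) while keeping a full run in tens of seconds. The
package defaults remain the operating values (5000 null locations,
100 px grid cells).

## γ-sensitivity

`run_gamma_sensitivity()` re-runs preprocessing, segmentation and
measurement at γ ∈ {0.70, 0.75, 0.80}. On the clean synthetic scenes the
classical backend is exactly γ-stable (spread 0 µm): the intensity
histogram is strongly bimodal, and monotone rescaling does not move pixels
across the threshold decision. On real SHG data, where fiber and
background intensities interleave, discrepancies on the order of 1 µm in
mean fiber length are the expected scale, and the harness reports the
spread and whether sample ranking is preserved.

## Known limitations

* The default segmentation backend is a classical threshold-and-thin
  pipeline; it under-segments dim or densely crossing fibers compared to a
  trained model. The backend interface exists precisely so a learned
  segmenter can be slotted in.
* The tissue mask is Otsu-based and may differ from manual annotation on
  weakly stained sections.
* Cross-modal registration with the default NCC metric assumes
  monotonically related intensities; use the MI metric otherwise. The
  synthetic brightfield shares no structure with the synthetic SHG frame,
  so registration validation uses same-structure pairs.
* Orientation SEM is a linearized dispersion of axial deviations; it is
  meaningful for concentrated distributions and conservative otherwise.
* No hypothesis tests across samples or probes are provided; profile
  comparisons are descriptive, with SEMs propagated in quadrature.
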