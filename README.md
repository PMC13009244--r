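# corrmap

Correlative mapping of RNAscope transcript dots and SHG collagen fiber
architecture in the same tissue section.

## The problem

Chromogenic RNAscope in-situ hybridization shows where individual
transcripts sit in a tissue section (discrete reddish dots in a brightfield
scan), and second-harmonic-generation (SHG) multiphoton microscopy images
the fibrillar collagen of the same section label-free. Analyzed together in
one coordinate frame, the two modalities can answer a question neither can
alone: does the local collagen architecture differ in the neighborhood of
transcript signals? This matters in fibrotic muscle disease (e.g. Duchenne
muscular dystrophy), where transcript distribution and matrix remodeling
may be spatially linked.

`corrmap` implements the full analysis chain in R:

1. **Dot detection** — a chromatic ratio map `G / (R + B + ε)` (ε = 0.001)
   is thresholded at 0.4; connected components of low-green-ratio pixels
   are transcript dots, summarized by centroid and area, normalized to
   dots/mm² over an Otsu-derived tissue mask.
2. **Fiber morphometrics** — the SHG image is γ-corrected (γ = 0.75) and
   2×2 median-filtered, segmented and skeletonized (pluggable backend;
   classical Sauvola default), split into junction-free branches, and each
   fiber is measured by:
   * length `L = Σ w_i · 0.63 µm` with axial step weight 1, diagonal √2,
   * orientation θ ∈ [0, π) of the endpoint-to-endpoint vector,
   * tortuosity τ = curvilinear length / Euclidean endpoint distance.
3. **Registration** — an intensity-based rigid (optionally affine)
   transform maps the brightfield into the SHG frame; dot centroids are
   carried across exactly (no resampling).
4. **Macroscale analysis** — 100×100 px grid aggregation of fiber
   properties and dot counts, with a Spearman correlation matrix across
   {length, orientation, tortuosity, dot count}.
5. **Microscale proximity analysis** — concentric radii 10–100 px
   (6.3–63 µm at 0.63 µm/px) around every dot; per-radius mean fiber
   count, mean length ± SEM, isolated-dot fraction; profiles normalized to
   the smallest radius with an OLS decay slope; and a **randomized null
   model** (pseudo-dots uniform over the tissue mask, default n = 5000)
   that exposes how much of any decay is pure sampling geometry.

A synthetic paired-scene generator with exact ground truth (analytic fiber
metrics, known dot centroids, known misalignment) makes every stage
testable without any imaging data.

## Worked example

```r
library(corrmap)

## paired synthetic sample: dots enriched near long fibers
fs  <- fiber_scene_spec(c(256, 256), n_fibers = 40,
                        length_range = c(6, 45), seed = 1)
shg <- generate_fiber_image(fs)
ds  <- dot_scene_spec(c(256, 256), n_dots = 30, seed = 2,
                      enrichment = list(fiber_table = shg$fiber_table,
                                        radius_px = 15,
                                        length_quantile = 0.6))
bf  <- generate_brightfield_image(ds)

fibers <- extract_fibers(shg$image)           # segment + measure
mask   <- compute_tissue_mask(bf$image)
dots   <- detect_dots(bf$image, dot_params(), mask = mask)

pp   <- proximity_params(n_random = 500, seed = 3)
prof <- proximity_profile(dots, fibers, pp)
prof[, c("radius_um", "mean_fiber_count", "mean_length_um",
         "isolated_fraction")]
```

```
   radius_um mean_fiber_count mean_length_um isolated_fraction
1        6.3        0.8333333       27.46138         0.2333333
2       12.6        1.8333333       25.25206         0.0000000
3       18.9        2.7000000       23.62879         0.0000000
...
10      63.0       17.4666667       22.02895         0.0000000
```

Mean fiber length falls from 27.5 µm in the immediate neighborhood of the
dots (6.3 µm radius) to 22.0 µm at 63 µm — the long fibers sit close to
the transcript signals, exactly as the generator coupled them. The null
model separates this from geometry:

```r
np   <- normalize_profile(prof)
null <- randomized_baseline(fibers, mask, pp)
c(experimental = profile_slope(np),
  baseline     = profile_slope(normalize_profile(null)))
```

```
 experimental      baseline
-0.0028527      -0.0014936      # per um
```

The experimental decay is about twice as steep as the
complete-spatial-randomness baseline: the association is not a sampling
artifact. On uncoupled scenes the two slopes are statistically
indistinguishable (see the test suite).

A thin CLI wraps the same functions
(`inst/scripts/corrmap simulate | detect-dots | segment-fibers | register |
grid | proximity | null-model | gamma-sens | run-all`), with configuration
in one YAML file (`default_config()` / `write_config()`).

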