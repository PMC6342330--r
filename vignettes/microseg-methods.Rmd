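---
title: "Clustering-based segmentation of microarray sub-grids: models and methods"
author: "microseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-based segmentation of microarray sub-grids: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microseg)
```

# The problem

A two-color cDNA microarray scan yields one 16-bit grayscale raster per
fluorescence channel (Cy3/red, Cy5/green). Each rectangular sub-grid
(block) carries a lattice of printed spots; the relative expression of
the gene at a spot is the log ratio of its background-corrected channel
intensities. Getting that number right hinges on *segmentation*:
deciding, pixel by pixel, which pixels belong to the hybridized spot and
which to the surrounding glass. Real scans complicate this with noise,
low contrast, missing spots, and non-circular spot morphologies (donuts,
comets, irregular blobs).

`microseg` implements an improved two-class clustering segmenter in two
flavors — IKM (improved K-means) and IFCM (improved fuzzy C-means) —
together with their traditional intensity-only baselines (KM, FCM), a
full pipeline from raw rasters to per-spot expression statistics, and a
seeded synthetic image generator with pixel-level ground truth for
quantitative evaluation.

# Pipeline overview

For one sub-grid the pipeline (`runPipeline()`) performs:

1. **Preprocessing scalars.** The fourth-moment contrast score
   $C = S_d / (F_{om}/M_{se}^2)^{1/4}$ and the background gray level $k$
   (mean over $m$ trials of the minimum over 12 border-window maxima)
   are computed on the channel sum.
2. **Denoising.** A 3×3 median filter with edge replication.
3. **Gridding.** Projection profiles on both axes are filtered by
   grayscale morphological reconstruction, thresholded at the maximum
   between-class variance (Otsu's criterion on the 1-D signal values),
   and converted into interior grid lines (gap midpoints) and
   boundary-line pairs (spot-band extents); heuristic revision enforces
   a quasi-uniform pitch. This yields the spot cells, the estimated spot
   diameter $d$ (mean grid pitch) and the rough spot size $s$ (mean
   boundary-pair width).
4. **Per-cell clustering.** The improved modes build a 9-feature
   per-pixel descriptor
   $F = [r, i, j, D_M, D_{Eud}, I, \bar I, \delta, E]$ — shape
   (correlation $r$ of the $d\times d$ neighborhood with a Gaussian spot
   template), spatial (coordinates and city-block/Euclidean distances to
   the cell center), and intensity/texture (intensity, 3×3 mean, 3×3
   mean squared deviation, 3×3 histogram entropy) — z-score it, fuse it
   to the top three principal components, and run two-class K-means or
   FCM (fuzziness $m = 2$, Euclidean distances, termination on maximum
   center movement). Initialization is data-driven: the background
   center is the reduced feature vector of the pixel whose intensity is
   nearest $k$, the foreground center the cell-center pixel's features
   with its intensity entry replaced by the 3×3 center-window mean. The
   baselines cluster the sole raw pixel intensity from two seeded random
   pixels.
5. **Adaptive refinement** (improved modes only; it is one of the
   improvements, so the baselines keep their raw masks). Foreground
   pixels outside a circle of diameter $s$ are removed as noise, and a
   spot is flagged missing when $n_c < 0.5\,(3.14\,s)$ or
   ($n_c \ge 3.14\,s$ and $n_f > 0.9\,n_s$), with $n_s$ the cell pixel
   count, $n_f$ the foreground count *before* removal, and $n_c$ the
   inside-circle foreground count. Counting $n_f$ before removal is
   deliberate: removal forces $n_f = n_c$, which would make the
   saturated-cell branch unreachable.
6. **Quantification.** Per spot: foreground/background means per
   channel over the (refined) mask, background-corrected intensities
   $I_{cy3} = R_{fore} - R_{back}$, $I_{cy5} = G_{fore} - G_{back}$, the
   log ratio $M = \log_2(I_{cy3}/I_{cy5})$, the mean log intensity
   $A = \tfrac12 \log_2(I_{cy3} \cdot I_{cy5})$, and a per-spot quality
   index $q_{index} = (q_{sig} \cdot q_{bkg1} \cdot q_{bkg2})^{1/3}$
   with $q_{sig} = F_{mean}/(F_{mean}+B_{mean})$, $q_{bkg1}$ the
   max-normalized, complemented background variability $BSD/B_{mean}$,
   and $q_{bkg2}$ the max-normalized background level ratio
   $bgk_0/(bgk_0+B_{mean})$. Non-positive corrected intensities and
   missing spots yield `NA` for $M$ and $A$ (counts are still
   reported). Pixel-level evaluation against a truth mask reports
   $acc = (TP+TN)/\text{total}$, $se = TP/(TP+FN)$ and
   $sp = TP/(TP+FP)$ — note $sp$ as defined here is the *precision* of
   the foreground call, kept deliberately in that form.

# Tunable parameters

| Knob | Default | Units | Role |
|---|---|---|---|
| `medianSize` | 3 | px | median filter window |
| `bgTrials`, `bgWindows`, `bgWindowSize` | 10, 12, 10 | —, —, px | background-estimate sampling |
| `markerDrop` | 0.1 | fraction of profile range | reconstruction marker drop |
| `bandFrac` | 0.25 | fraction | gap-trim level for boundary placement |
| `sigmaRule` | 0.25 | fraction of $d$ | Gaussian template $\sigma = d/4$ |
| `mFuzz` | 2 | — | FCM fuzziness exponent |
| `tol`, `maxIter` | 1e-5, 100 | —, — | clustering termination |
| `missingRule` | `"linear"` | — | printed $3.14\,s$ rule vs circle-area variant |
| `circleCenter` | `"centroid"` | — | refine circle anchoring |
| `applyEnhancement` | `FALSE` | — | route contrast enhancement into gridding |
| `entropyBins` | 256 | bins | entropy histogram resolution |
| `seed` | 1 | — | all stochastic elements |

The entropy histogram uses 256 equal-width bins (16-bit values
right-shifted by 8): at full 16-bit depth nearly every 3×3 window value
is a singleton and the entropy saturates at $\log_2 9$ for all pixels,
carrying no information. `entropyBins = 65536` restores the full-depth
reading.

Features are z-scored before PCA because their native scales differ by
orders of magnitude (correlations in $[-1,1]$, coordinates in tens,
intensities in tens of thousands); without standardization the fusion
would be an intensity filter. PCA is fit per spot cell, matching the
per-cell clustering; zero-variance columns (e.g. on constant cells) are
dropped, eigenvector signs are fixed by making each component's
largest-magnitude loading positive, and fewer than three informative
columns pad the scores with zeros.

# Design choices made where the design was open

**Contrast enhancement and its place in the pipeline.** The enhancement
rule multiplies every pixel at or below $k$ by $10000/C$ and leaves
brighter pixels untouched. When the image's whole dynamic range sits at
or below $k$ — the low-contrast regime the rule is meant for — it is a
near-uniform rescale, and the gridding chain is scale-invariant, so
nothing downstream changes. When $k$ falls *inside* the foreground
intensity distribution (low-contrast spots under heavy noise put the
min-of-max estimate right at the foreground level), the rule inverts
intensity ordering across the branch seam: part of the foreground is
multiplied past the background while the rest stays put, and projection
profiles can flip (spot bands become apparent gaps). The default
pipeline therefore computes and reports $C$ and $k$ but grids and
clusters the un-enhanced denoised raster;
`pipelineConfig(applyEnhancement = TRUE)` restores the literal routing.
Expression is always quantified on un-enhanced denoised channels — an
enhanced scale would corrupt the ratios.

**Boundary lines.** The between-class threshold sits well inside a spot
band's profile (a disc's outer rows have short chords), so raw
threshold crossings under-measure the spot by about 2 px and the
refinement circle would clip genuine spot pixels. Each sub-threshold
gap run is therefore trimmed back to its background envelope: end
samples above `min(run) + bandFrac * (thresh - min(run))` are
reassigned to the adjacent band before lines and boundaries are placed.
`bandFrac = 0` keeps the raw crossings.

**Marker drop.** The reconstruction drop is a fraction of the profile
range. A large drop (0.3) can exceed the prominence of a weak spot band
(a column with several missing spots on a low-contrast image) and erase
its band below the threshold, losing a whole grid line; 0.1 flattens
profile noise while preserving weak bands, and is the pipeline default.

**Cell tiling.** Outer cell edges extend one pitch beyond the outermost
interior grid lines (clipped to the image) rather than stopping at the
outer boundary lines, so border cells are centered on their spots like
interior cells; off-center border cells would otherwise put the
refinement circle off the spot.

**Refinement circle anchoring.** The circle is centered on the centroid
of the cell's recognized foreground (before noise removal) by default.
Anchoring on the cell's geometric center (`circleCenter = "cell"`)
makes the circle inherit any gridding jitter — a ±1 px line error
directly clips true disc edges. With no foreground the circle falls
back to the cell center.

**Distances to the cell center.** $D_M$ and $D_{Eud}$ are measured to
the exact geometric center (half-integer for even-sized cells). Using a
rounded center pixel skews the spatial features asymmetrically about
the spot, which propagates into an asymmetric membership field. The
rounded center pixel is still used where an actual pixel is required
(the 3×3 foreground-initialization window).

**Foreground identity and degenerate cells.** After clustering, the
foreground is the cluster with the strictly higher mean raw intensity.
Equal means carry no intensity evidence of a spot (constant,
background-only cells) and yield no foreground; an empty background
cluster marks the saturated all-foreground failure mode, which the
missing rule then flags. Assignment and membership ties resolve to the
background-initialized cluster, and a pixel coincident with a center
receives crisp membership (the membership formula is singular there).

**Baselines.** The baselines cluster the raw channel-sum intensities:
median denoising belongs to the proposed preprocessing, and the noise
sensitivity of plain KM/FCM — the behavior the improved methods are
measured against — exists only on unfiltered data. Gridding and
quantification are shared across all modes so that the comparison
isolates the clustering and refinement.

**Spot size formula.** The per-axis sums of boundary-pair widths are
averaged (`sFormula = "mean"`), consistent with the per-spot definition
$s_i = \tfrac12[(H^0_{2i}-H^0_{2i-1}) + (V^0_{2i}-V^0_{2i-1})]$; the
literal summed reading (which doubles the scale) is available as
`sFormula = "sum"`.

**Missing rule scale.** The printed thresholds $3.14\,s$ and
$0.5\,(3.14\,s)$ scale linearly with the diameter while pixel counts
scale quadratically; the rule is implemented exactly as printed, with
`missingRule = "area"` offering the circle-area reading
$3.14\,(s/2)^2$.

# The synthetic generator

`generateSubgrid()` renders an $n_R \times n_C$ lattice of cells
(default pitch 20 px, nominal spot diameter 12 px) in two channels.
Per spot, a shape is drawn from `shapeMix` — circle, donut (annulus
with inner radius $0.45\,r$), comet (disc plus a linearly decaying
off-spot tail), irregular (periodic radius perturbation, uniform within
±25% of nominal), or missing (background-only cell) — and a true log
ratio is drawn $N(0, mSd)$. Foreground pixels carry
background + excess, with the channel excesses
$e_{cy3} \propto 2^{M/2}$, $e_{cy5} \propto 2^{-M/2}$, so the true $M$
is defined from pre-noise means, independent of the pipeline's own
extraction. Additive Gaussian noise (clipped to the 16-bit range) is
applied per channel. The truth mask marks exactly the constant-excess
pixels; comet tails are deliberately *not* truth foreground — they
model contamination the segmenter should reject.

Three presets fix the study conditions: **good** (background 500,
foreground 10000, noise sd 100, 2% missing, mostly circles), **normal**
(800 / 4000 / 150 / 5% missing) and **poor** (1000 / 1400 / 200 / 10%
missing, half the spots non-circular). The poor levels put the
foreground within two noise standard deviations of the background. The
per-spot log-ratio spread is 0.4 in all presets, a typical biological
dispersion that leaves extreme values ($|M| > 2$) rare.

What the generator does **not** emulate: intensity gradients inside
spots and soft edges (spots are hard-edged), spatially correlated noise
and scanner artifacts, background trends across the slide, grid
rotation or pin-geometry distortions, and saturation blooming. Passing
tests on these images therefore demonstrate the algorithmic properties
of the chain — grid recovery, initialization, clustering behavior,
refinement logic, expression algebra — not performance on any real
scanner's output.

Because the generated block fills the raster edge-to-edge (no glass
margin), every border window used by the background estimator overlaps
spot pixels, and $k$ lands near the foreground level on high-contrast
images; even on pure glass the min-of-max statistic sits about two
noise standard deviations above the background mean (it estimates a
background *ceiling*, which is what the enhancement branch and the
background-center initialization need). The end-to-end results are
insensitive to this because the foreground-identity rule relabels
clusters by mean intensity regardless of where $k$ fell.

# Numerical choices and degenerate inputs

* Otsu candidates are the distinct signal values, classes split as
  $x < t$ versus $x \ge t$, ties broken toward the lower threshold;
  constant signals are a degenerate-threshold error.
* Reconstruction uses alternating forward/backward raster sweeps of the
  geodesic dilation until stable — exact, and fast for profile-length
  signals.
* The 3×3 median uses an exact 19-exchange min/max network, vectorized
  over pixels; all windows (median, local statistics, correlation)
  replicate edges.
* Pixels at distance exactly $s/2$ from the circle center count as
  inside.
* Clustering terminates on maximum absolute center movement
  (`tol = 1e-5`), capped at 100 iterations; the FCM objective
  $J = \sum_{ij} u_{ij}^m d_{ij}^2$ is recorded per iteration and is
  non-increasing. K-means re-seeds an emptied cluster at the point
  farthest from the other center.
* The improved path is fully deterministic; the only randomness in the
  pipeline (background-window draws, baseline initialization) is driven
  by the configured seed, so identical configurations reproduce outputs
  byte-for-byte.

# Problem sizes used by the checks

The test-suite and the acceptance script run at desk scale, chosen to
exercise every preset while keeping a laptop run in minutes: 12 images
(10×10 spots, 200×200 px, four seeds per preset) for the sensitivity
claim, ten seeds of the normal preset for the improved-versus-baseline
ordering, 50 random small datasets for the FCM fixed-point check, 20
for the K-means fixed-point check, and ten noise-free seeds for grid
recovery. Oracles are coded independently of the implementation
(loop-based fixed-point iterators, exhaustive sweeps, brute-force
window statistics), with `stats::kmeans` and `e1071::cmeans` as
external cross-checks.

# Known limitations

* Single sub-grid per invocation; multi-block slide partitioning and
  rotation correction are out of scope.
* The refinement circle removes genuine signal from spots wider than
  $s$ (strongly irregular morphologies); this is inherent to the circle
  rule and is the dominant residual sensitivity loss on the noisy
  presets.
* Missing-spot detection under heavy noise is conservative: a
  background-only cell whose noise splits into a plausible spot-sized
  cluster inside the circle is kept (and contributes false positives to
  the precision figure rather than being imputed).
* Background correction is local (cell-level means); no spatial
  background surface is fit.
* $sp$ follows the printed definition (precision), not the
  conventional true-negative rate; comparisons with other tools should
  account for this.
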