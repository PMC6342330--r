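# microseg

Clustering-based segmentation and quantification of two-channel cDNA
microarray sub-grid images, for bioinformaticians and image-analysis
researchers who need per-spot expression values with pixel-level
control over the segmentation.

Spotted microarrays measure relative gene expression as the ratio of
two fluorescence channels (Cy3/Cy5) at each printed spot. The step that
decides which pixels belong to a spot — segmentation — dominates the
quality of the extracted ratios, and plain clustering segmenters
(K-means, fuzzy C-means on raw pixel intensity) are notoriously
noise-sensitive. `microseg` implements an improved clustering chain:

* **Gridding** by projection profiles: morphological-reconstruction
  filtering, maximum between-class-variance (Otsu) thresholding of the
  1-D profile, gap-midpoint grid lines, boundary-line pairs around each
  spot band, and heuristic pitch revision — yielding spot cells, the
  estimated spot diameter *d* and rough spot size *s*.
* **Multi-feature clustering**: every pixel carries the 9-vector
  `[r, i, j, D_M, D_Eud, I, Ibar, delta, E]` (Gaussian-template shape
  correlation; coordinates and city-block/Euclidean distances to the
  cell center; intensity, 3×3 mean, 3×3 squared deviation, 3×3
  histogram entropy), z-scored and fused to three principal components.
  Two-class K-means (IKM) or fuzzy C-means (IFCM, memberships
  `u_ij = 1 / Σ_k (d_ij/d_kj)^(2/(m-1))`, centers
  `c_i = Σ_j u_ij^m x_j / Σ_j u_ij^m`) start from data-driven centers:
  the pixel nearest the estimated background gray level *k* for the
  background, the cell-center 3×3 neighborhood for the foreground.
* **Adaptive refinement**: foreground outside a circle of diameter *s*
  is removed as noise; a spot is flagged missing when
  `n_c < 0.5·(3.14·s)` or (`n_c ≥ 3.14·s` and `n_f > 0.9·n_s`).
* **Quantification**: background-corrected intensities
  `I_cy3 = R_fore − R_back`, `I_cy5 = G_fore − G_back`, log ratio
  `M = log2(I_cy3/I_cy5)`, mean log intensity
  `A = ½·log2(I_cy3·I_cy5)`, per-spot quality index
  `q_index = (q_sig · q_bkg1 · q_bkg2)^(1/3)`, and pixel-level
  `acc`/`se`/`sp` against a truth mask.
* **Synthetic data**: a seeded generator of two-channel sub-grids with
  pixel-level ground truth (circle/donut/comet/irregular/missing spot
  shapes; good/normal/poor quality presets) plus intensity-only KM/FCM
  baselines and a benchmark harness, so every claim about the improved
  methods is measurable.

See the methods vignette (`vignettes/microseg-methods.Rmd`) for the
models, parameter semantics and design decisions.

## Worked example

```r
library(microseg)

params <- qualityPreset("normal", nRows = 6, nCols = 6, seed = 42)
sg <- generateSubgrid(params)
sg
#> MicroarraySubgrid: 120 x 120 px, 6 x 6 spots (normal preset)
#>   truth: 3705 spot pixels, 2 missing spot(s)

res <- runPipeline(sg, mode = "ifcm")
res
#> SubgridSegmentation [ifcm]: 120 x 120 px, 36 spots (0 missing)
#>   foreground pixels: 4053; C = 2329.95, k =  4592.7

unlist(evaluateMask(segMask(res), truthMask(sg)))
#>           TP           TN           FP           FN          acc           se
#> 3.652000e+03 1.029400e+04 4.010000e+02 5.300000e+01 9.684722e-01 9.856950e-01
#>           sp
#> 9.010609e-01

head(spotQuant(res)[, c("row","col","NFore","Icy3","Icy5","M","A",
                        "qIndex","isMissing")], 4)
#>   row col NFore     Icy3     Icy5           M        A    qIndex isMissing
#> 1   1   1   115 3598.944 2359.578 0.609045082 11.50884 0.3414956     FALSE
#> 2   1   2   114 3101.318 3095.782 0.002577638 11.59738 0.9064509     FALSE
#> 3   1   3   113 3329.874 2949.042 0.175221421 11.61364 0.9036856     FALSE
#> 4   1   4   112 3456.776 2918.086 0.244405078 11.63301 0.9091471     FALSE
```

Reading the output: the IFCM segmentation recovered 98.6% of the true
spot pixels (`se`) at 96.8% pixel accuracy on a mid-quality image; the
401 false positives are mostly noise clusters in the two truly missing
cells, which depress the foreground precision (`sp`, as defined here)
to 0.90. Per spot, `M` is the background-corrected log2 expression
ratio (spot (1,1) is ~1.5-fold up in Cy3), `A` the mean log intensity,
and `qIndex` a [0,1] quality score combining signal-to-noise with two
background-regularity components — note how spot (1,1), whose local
background is much more variable than its neighbors', scores far
lower. `truthTable(sg)` holds the
generator's per-spot truth (`trueM`, `isMissing`) for comparison, and
`runBenchmark()` repeats this across presets, seeds and all four modes
(`km`, `ikm`, `fcm`, `ifcm`).

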