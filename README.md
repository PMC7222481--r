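# cardioseg

Fully automated single-cell segmentation and phenotype quantification for
dual-channel fluorescence micrographs of stem-cell-derived cardiomyocytes
(nuclear stain + sarcomeric α-actinin).

Quantifying drug-induced cardiotoxicity at the single-cell level requires
segmenting individual cardiomyocytes in cultures where cells grow in
clustered monolayers and express α-actinin very unevenly: the cytoplasmic
channel shows a background-dominated, uni-modal intensity histogram with a
long bright tail.  A conventional global Otsu threshold lands high on such
histograms and silently discards weakly stained cells.  `cardioseg`
replaces it with histogram-accelerated fuzzy C-means masking and
propagates nucleus seeds to delineate the individual cells.

## The pipeline

1. **Preprocessing** — per channel: rolling-ball background subtraction
   (radius 100 cytoplasm / 50 nuclear), Gaussian smoothing (radius 5 / 2),
   disc median filter (radius 5, cytoplasm), linear contrast stretch
   saturating 0.3% of cytoplasm pixels.
2. **Nucleus seeds** — Otsu threshold of the nuclear channel, watershed on
   the Euclidean distance transform to split touching nuclei, and a
   radius-1 closing-based merge so the twin nuclei of bi-nucleated
   cardiomyocytes act as one seed.
3. **Cell mask (EnFCM)** — fuzzy C-means over the gray-level histogram,
   minimizing

   $$J=\sum_{i=1}^{C}\sum_{l=1}^{q} h_l\,u_{il}^{m}(l-C_i)^2,\qquad m>1,$$

   with the closed-form membership/center updates; cost per iteration
   scales with the number of gray levels q, not pixels.  Foreground =
   every gray level whose combined membership outside the background
   cluster reaches 0.5.  A pixelwise FCM (`fcm_fit_pixelwise()`) is
   shipped as the correctness oracle, and `mask_cells_otsu()` as the
   conventional comparator.
4. **Seeded propagation** — multi-source lowest-cost growing through the
   mask with step cost `sqrt(dI^2 + lambda * step^2)` (intensity
   normalized to [0,1]; `lambda = 1` balances both terms), deterministic
   tie-breaks.
5. **Phenotypes** — area, Crofton perimeter, mean intensity; moment-based
   shape (elongation, compactness `4*pi*A/P^2`, extension, dispersion,
   axes); histogram texture (std, smoothness, skewness, uniformity,
   entropy) per channel; cell-cell contact; nuclear intensity CV.
6. **Evaluation & statistics** — pixel precision/recall/F-score with
   mean/SEM aggregation, nuclei-count correctness, and per-feature
   two-sample Kolmogorov–Smirnov dose-response reports against vehicle
   control.

A synthetic dual-channel scene generator (`generate_scene()`,
`generate_dose_series()`) with exact ground truth makes the whole system
testable end to end without external data.

## Worked example

```r
library(cardioseg)

sc  <- generate_scene(scene_params(seed = 1))   # 512x512, ~54 cells, truth masks
seg <- run_segment(sc$pair)                     # preprocess -> seeds -> EnFCM -> propagate
seg$log$n_seeds                                 # 54
seg$log$n_cells                                 # 54
attr(seg$cell_mask, "threshold")                # 36 (EnFCM cut-off, gray levels)

truth_fg <- matrix(as.integer(sc$truth$cell_labels > 0), 512, 512)
pixel_prf(matrix(as.integer(seg$cells > 0), 512, 512), truth_fg)
#> precision 0.833  recall 0.974  F 0.898

tab <- measure_image(seg$cells, sc$pair, seg$seeds, "scene1", "control")
head(tab[, c("cell_id", "area", "perimeter", "elongation",
             "compactness", "contact_fraction", "nuclear_cv")], 4)
#>   cell_id area perimeter elongation compactness contact_fraction nuclear_cv
#> 1       1 3009   205.915      0.082       0.892            0.249      0.218
#> 2       2 3736   239.568      0.318       0.818            0.169      0.244
#> 3       3 2503   204.193      0.255       0.754            0.397      0.236
#> 4       4 2242   171.689      0.279       0.956            0.061      0.240
```

All 54 planted cells are recovered (one seed each; the propagation cannot
invent labels), the EnFCM cut-off (36) sits far below the Otsu threshold
(95 on the same image), and the pixel F-score against the planted ground
truth is 0.90.  `dose_response_report()` then turns per-condition feature
tables into mean ± SEM with KS significance flags, and expresses
per-image cell counts as percent of control — the viability read-out.

A thin command-line front end (`inst/cli/cardioseg`) exposes `segment`,
`features`, `evaluate` and `simulate` subcommands over TIFF/CSV files.

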