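---
title: "Segmenting and phenotyping cardiomyocyte micrographs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and phenotyping cardiomyocyte micrographs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioseg)
```

## The problem

Immunofluorescence screens of stem-cell-derived cardiomyocytes stain the
nucleus (DAPI-like channel) and sarcomeric α-actinin (cytoplasmic
channel).  Quantifying drug-induced phenotypes at the single-cell level
requires segmenting individual cells, which is hard for two reasons: the
cells grow in clustered monolayers with weak edges between neighbours, and
α-actinin expression varies strongly both within and between cells, so the
cytoplasmic channel shows a background-dominated, uni-modal intensity
histogram with a long bright tail rather than a clean bimodal mixture.  A
single global threshold chosen by between-class variance (Otsu) lands high
on such histograms and discards weakly stained cells wholesale.

`cardioseg` implements a fully automated pipeline: channel conditioning,
nucleus seed detection, fuzzy-clustering cell masking, and seeded
propagation, followed by a phenotype feature suite and dose-response
statistics.  A synthetic scene generator with exact ground truth makes
every stage testable without any external image data.

## Preprocessing

Each channel is conditioned independently with standard radii (pixels on
the stored raster): rolling-ball background subtraction (radius 100
cytoplasm / 50 nuclear, implemented as grayscale opening with a disc),
Gaussian smoothing (radius 5 / 2, where "radius" is the Gaussian standard
deviation — the convention of the common interactive tools, so published
settings carry over), a radius-5 disc median filter (cytoplasm only), and
a linear contrast stretch saturating 0.3% of cytoplasm pixels (half at
each end of the intensity range).  The stage order is background
subtraction, Gaussian, median, contrast.  Linear normalization was chosen
over histogram equalization for the contrast step; equalization would
reshape the histogram that the downstream clustering models.  Borders use
replicate padding.  All radii are exposed in the `preprocess` block of the
pipeline configuration.

## Cell masking by histogram-accelerated fuzzy C-means

Fuzzy C-means assigns each gray level a membership in each of C clusters.
The accelerated variant (EnFCM) clusters the gray-level histogram rather
than individual pixels, minimizing

$$J \;=\; \sum_{i=1}^{C}\sum_{l=1}^{q} h_l\, u_{il}^m (l - C_i)^2,\qquad m>1,$$

with $h_l$ the pixel count at level $l$, by alternating the closed-form
membership and center updates.  Iteration cost scales with the number of
gray levels $q$ (default 256, binned over the observed intensity range),
not with pixel count, so a montage-sized image costs the same per
iteration as a thumbnail; the histogram build is the only pixel-bound
step.  With $q$ spanning the full gray range the fixed point is
algebraically identical to pixelwise FCM, which the package also ships
(`fcm_fit_pixelwise()`) as the correctness oracle.  Initialization is
deterministic (weighted quantile centers), tolerance $10^{-4}$ gray
levels on the maximum center shift, 300-iteration cap.

The mask cut-off is the smallest gray level whose combined membership in
the non-background clusters reaches 0.5.  The cluster count matters more
than any other parameter:

* With **C = 2** the 0.5-membership crossing is exactly the midpoint of
  the two centers (for any fuzzifier, since the crossing sits where the
  two squared distances are equal).  On background-dominated long-tail
  histograms this midpoint tracks the global Otsu threshold within a few
  gray levels, so two-cluster fuzzy masking inherits Otsu's failure on
  weakly stained cells.
* With **C = 3** the middle cluster drifts between the dim-periphery and
  weak-cell populations from image to image, making the cut-off unstable.
* With **C = 4** (the default) the model resolves background, dim cell
  periphery, weakly stained cells and strongly stained cells; the cut-off
  settles at the background/dim boundary, well below the Otsu threshold,
  and weakly stained cells are retained.  This is the property that makes
  the fuzzy approach outperform global Otsu masking on heterogeneous
  α-actinin signal.

`mask_cells_otsu()` provides the conventional Otsu mask as a comparator;
the fuzzifier (default $m=2$), $q$ and C are all configurable.

## Nucleus seeds

The nuclear channel is thresholded by Otsu's criterion (appropriate there:
nuclei are compact and bright, the histogram effectively bimodal), objects
under 50 px² are discarded as debris (the value is configurable; the
choice only needs to sit below the smallest plausible nucleus, ~150 px² at
this scale), and touching nuclei are split by a watershed on the negated
Euclidean distance transform seeded at its regional maxima with an
h-maxima suppression of one distance unit to avoid plateau fragmentation.
A grayscale-watershed variant (`split_nuclei_grayscale()`) is included as
a comparator: when intra-nuclear intensity is uneven it overcuts nuclei,
which is why the distance-based method is the default.  Finally, nuclei
whose supports become connected under a radius-1 morphological closing are
merged into one seed, so closely apposed twin nuclei of bi-nucleated
cardiomyocytes propagate as one cell; `merge_radius` is exposed because
one closing of radius 1 is the literal reading of "consecutive one pixel
dilation and erosion", but denser cultures may warrant 0.

## Seeded propagation

Cells are delineated by multi-source lowest-cumulative-cost growing from
the nucleus seeds through the cell mask.  A step from pixel $p$ to
neighbour $n$ costs

$$\sqrt{\Delta I(p,n)^2 + \lambda\,\mathrm{step}^2},$$

with intensities normalized to $[0,1]$ by the image's full range so that
$\lambda = 1$ (the default) gives the intensity and distance terms equal
impact, 8-connectivity with $\sqrt2$ diagonal steps, and ties broken
toward the lowest seed id at $10^{-12}$ cost resolution so output is
deterministic.  As $\lambda \to \infty$ the partition converges to the
geodesic Voronoi diagram of the mask; as $\lambda \to 0$ boundaries lock
onto intensity edges.  The exact functional form is pinned by an
independent shortest-path oracle in the test suite rather than by any
reference implementation.  Growth never leaves the mask (which is first
augmented with the seed support so every nucleus can initiate growth);
mask components containing no seed remain background and are counted as
debris; seeds wholly outside the mask are logged as orphans.

## Phenotype features

Per cell: area (pixel count), perimeter (4-direction Cauchy–Crofton
estimator, nearly unbiased on smooth shapes — a rasterized disc of radius
64 measures within 1% of $2\pi r$; the naive boundary-pixel count is
available separately), mean intensity; ellipse axes from second-order
central moments (full lengths $4\sqrt{\lambda_i}$), elongation
$1 - \text{short}/\text{long}$, compactness $4\pi A/P^2$ (the stated
circularity of a circle is 1, which requires the factor $\pi$; the
Crofton perimeter is what makes the disc anchor test pass), extension
$\log_2(\text{long}/\text{short})$ and dispersion $\log_2$ of the mean
radial distance over the equivalent-disc radius (a disc scores
$\log_2(2/3)$); five histogram texture features (std, smoothness,
skewness, uniformity, entropy) computed on 256-bin per-region histograms
normalized to the region's own $[\min,\max]$, emitted for both channels
with `_cyto`/`_nuc` suffixes since either channel can carry the relevant
texture; cell-cell contact (fraction of boundary pixels whose
8-neighbourhood contains a different cell — a monolayer-integrity proxy)
and the nuclear coefficient of variation (sd/mean of nuclear intensity
over the cell's seed region — elevated under chromatin condensation).

## Evaluation and dose-response statistics

Segmentation quality is scored pixelwise: precision, recall and
F-score (harmonic mean) per image, aggregated image-then-mean with SEM
(pooled-pixel aggregation is available but not the default; note the mean
F-score is not the F of the mean precision and recall).  Nuclei-count
correctness uses a one-to-one majority rule: a reference nucleus is
correct iff exactly one prediction claims more than half of its pixels
and that prediction claims no other nucleus — merged and overcut nuclei
both fail.  This rule is the package's own formalization of "correctly
segmented".

Treated conditions are compared with vehicle control feature-by-feature
with the two-sample Kolmogorov–Smirnov test at $\alpha=0.05$ (exact
p-values for small tie-free samples, asymptotic otherwise), with no
multiplicity correction by default — the screening convention — and an
optional Benjamini–Hochberg adjustment.  Per-image cell counts are
summarized as percent of the control mean, the viability read-out.

## The synthetic scene generator

The generator emulates the imaging regime the pipeline targets, with
exact ground truth.  Defaults are one 512×512 field at 0.64 µm/px (a 20×
objective on a montage-tiling CCD); the plating-density regimes translate
to ~54 cells ("spread", ~500 cells/mm²) or ~215 cells ("clustered",
~2000 cells/mm²).  Cells are randomly oriented ellipses, semi-major axis
28–42 px (≈1000–1400 µm², immature stem-cell-derived cardiomyocyte
scale), packed to ≈50% cover so neighbours touch; overlaps resolve to the
nearer cell, producing contiguous monolayers with weak edges.  A quarter
of cells are weakly stained at 30% of the strong amplitude (0.72 of full
scale, with lognormal sd 0.2 between-cell jitter); intensity is modulated
by a period-6 px sinusoidal striation standing in for Z-disc periodicity
and a mild radial taper ($1 - 0.15\,d^2$).  Fifteen percent of cells are
bi-nucleate with abutting twin nuclei (so seed merging is exercised);
nuclei are 7–10 px blobs.  Noise is Poisson shot noise plus Gaussian read
noise (sd 3) over a smooth aspecific background field.  Dose effects
plant cell loss, shrinkage, rounding and nuclear condensation
(smaller/brighter/more variegated nuclei); the standard titration
(`dose_conditions()`) makes all four monotone across five doses, with
five replicates per condition.

These scenes reproduce the qualitative regime that matters — the
background-dominated long-tail histogram on which Otsu drops weak cells
while the fuzzy mask keeps them — but not every property of real
micrographs: there is no optical point-spread model, no montage seams, no
out-of-focus debris, and striation is a pure sinusoid.  Passing tests
demonstrate correctness of the algorithms under these conditions, not
instrument-level performance on real screens.

## Numerical choices and degenerate inputs

Histogram binning uses a nearest-level rule so the extreme levels sit
exactly on the observed min/max; an integer image with one level per gray
value makes the accelerated and pixelwise fits agree to machine
precision.  Constant images are degenerate for thresholding and histogram
construction and raise errors at the operation level, while the pipeline
treats a blank channel as "no cells" and returns empty masks.  A gray
level coinciding exactly with a center receives full membership there.
Watershed ridge pixels are assigned to adjacent basins so no foreground
pixel is left unlabeled.  Cost ties in propagation go to the lowest seed
id.  Feature measurement floors the short ellipse axis at 1 px for
degenerate (collinear) regions.  CSV serialization uses 17 significant
digits so tables round-trip at machine precision.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on: 64×64 images for
the clustering equivalence (20 random images) and propagation oracle
(two-seed fixtures, $\lambda \in \{0.01, 1, 100\}$); 512×512 scenes for
end-to-end recovery (10 spread-regime scenes) and the 6-condition × 5-replicate
dose series.  These sizes were chosen so the whole suite runs in minutes
on one core while each check still exercises the full algorithmic path;
the pipeline itself streams per image and handles montage-scale rasters.

## Known limitations

The cluster count C must match the number of intensity strata; cultures
with yet broader expression continua may need C > 4 or a spatially
regularized variant (out of scope here).  The propagation cost is pinned
to the stated equal-impact contract, not to any particular legacy
implementation.  Densely clustered cultures can fuse adjacent-cell nuclei
into one seed (under-segmentation); the closing-based merge cannot
distinguish a bi-nucleate pair from two squeezed neighbours.  No physical
calibration is applied to features; all units are pixels.
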