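---
title: "Quantifying fungal pellet morphology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fungal pellet morphology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletmorph)
```

## The problem

Filamentous fungi such as *Aspergillus niger* grow in submerged culture as
roughly spherical pellets: spores agglomerate, germinate, and hyphae grow
radially outward. Pellet diameter and internal architecture strongly
influence nutrient transfer and product secretion, so quantifying them —
per pellet, per flask, and across replicate flasks — is a core task of
morphological process development. `pelletmorph` implements that
quantification as a tested pipeline over three levels:

1. **Macromorphology (2D):** segment pellets in stereomicrographs, compute
   each pellet's area-equivalent diameter
   $ED = 2\sqrt{A/\pi}$, and characterise the population.
2. **Population statistics:** median diameter, interquartile range (IQR) as
   the intra-flask heterogeneity measure, number-density ($q_0$) histograms
   on a fixed grid, and the distribution-free overlap coefficient
   $\mathrm{OVL}(A,B)=\sum_{i=1}^{80}\min\!\big(f_A(d_i),f_B(d_i)\big)$
   as the flask-to-flask reproducibility measure.
3. **Micromorphology (3D):** from voxelised pellet volumes, the radial
   solid-fraction profile about the mass centre, spore-core detection by
   density-based clustering, a three-class core typology (single core,
   multiple cores, fusion of mature pellets), the volume-equivalent
   diameter $(6V/\pi)^{1/3}$, and hyphal skeleton metrics (total length,
   tips, branch points).

Because the study-scale image and tomography data behind these methods are
not redistributable, the package ships a first-class synthetic-data
generator whose outputs carry exact ground truth. Every downstream stage is
validated against that ground truth; the generator is therefore part of the
tested surface, not a fixture.

## 2D segmentation model

The pipeline mirrors standard morphological-segmentation practice for
bright, touching, roughly convex particles:

* **Red channel.** Pellets contrast well against the background in the red
  channel and most debris does not; segmentation starts there.
* **Reconstruction filtering.** Opening-by-reconstruction (erosion with a
  disk of radius `open_se_px = 10` px, then reconstruction by dilation
  under the original) removes bright objects smaller than the structuring
  element; closing-by-reconstruction (`close_se_px = 5` px, computed by
  complementation) fills small dark holes. Unlike plain opening/closing,
  reconstruction restores the exact contours of surviving objects, which
  matters because areas become diameters. The composite filter is a
  morphological filter in the algebraic sense: applying it twice changes
  nothing, which the tests check.
* **Markers and mask.** After filtering, each pellet carries one
  flat-topped intensity plateau; the regional maxima (8-connected plateaus
  with no brighter neighbour) are the watershed markers. The pellet mask is
  an Otsu binarisation of the filtered image. The field's practice leaves
  the binarisation operator open; Otsu was chosen because it needs no
  illumination-dependent tuning, and the threshold is overridable.
* **Watershed split.** The mask is Euclidean-distance-transformed and
  negated; marker components are imposed as minima; priority flooding
  assigns every mask pixel to a basin. Ties at equal priority resolve by
  insertion order, so tied fronts advance evenly — resolving ties by label
  id instead lets the lower label sweep whole equal-distance shells and
  shifts the ridge measurably off the geometric waist, which is why that
  variant was rejected.
* **Post-filter.** Labels touching the image border are removed (their
  areas are censored), and only equivalent diameters in
  `[d_min, d_max] = [100, 3000]` µm are kept; anything outside is unlikely
  to be a single pellet.

Each flask replicate is analysed as **two independently prepared aliquot
images** whose record sets are pooled under distinct sub-sample ids. For a
deterministic pipeline, re-running the same image twice would be a no-op;
two aliquots is the reading that adds information.

**Pixel calibration matters.** The opening element erases objects smaller
than about twice its radius, so at 10 µm/px everything below ~200 µm
disappears before measurement. The study drivers therefore calibrate the
pixel size per condition (4 µm/px where the population median is below
480 µm, 10 µm/px otherwise), keeping the 100 µm admissibility limit above
the filter's erasure scale wherever such pellets can occur. With that
calibration the pipeline recovers every admissible synthetic pellet in the
shipped analysis; without it, small-pellet conditions lose their lower
quartile silently.

## Population statistics

Medians and IQRs use linear interpolation between order statistics
(`quantile` type 7). Populations with fewer than 30 analysed pellets are
flagged `excluded` — too few pellets to characterise a distribution — and
any OVL pair involving such a population is set to 0. The $q_0$ grid is
fixed: 0–4000 µm in 50 µm classes (80 bins, half-open `[lo, hi)`);
diameters at or above 4000 µm cannot occur after the 3000 µm post-filter
but are dropped with a warning if present in manually measured records.

**Modality.** Unimodal/multimodal is a visual call in practice; the
package's operationalisation smooths the density with a 3-bin moving
average and counts peaks whose topographic prominence exceeds 10 % of the
maximum smoothed density *plus* `noise_z = 2.5` binomial standard errors of
the smoothed peak height. The noise term is essential: without it, the
sampling jitter of a wide distribution histogrammed into 50 µm bins at
n ≈ 40 reads as "multiple distinct peaks" for the vast majority of genuinely
unimodal populations. All three knobs are exposed, and the flag is reported
rather than silently acted on.

## Diameter regression

The regression models ln(median ED) per flask replicate on cultivation
parameters. Spore concentration and shaking frequency are ln-transformed
(putting the decade-spaced spore titres on a linear scale); talc
concentration stays in g/L; baffling is a 0/1 indicator. Replicates enter
as independent observations — a deliberate simplification that ignores
intra-flask pseudo-replication and is inherited from the modelling
convention the package follows. Excluded and multimodal populations are
dropped before fitting.

Fitting is ordinary least squares via `stats::lm`. The package adds:

* **Diagnostics** as data plus two descriptive scores: a
  heteroscedasticity score (Pearson correlation of |residual| with fitted;
  a funnel gives a large positive value) and a normality statistic
  (correlation of sorted residuals with normal quantiles). Both
  operationalise otherwise visual judgements and are reported, never
  auto-enforced.
* **Multicollinearity:** the predictor correlation matrix and variance
  inflation factors $VIF_j = 1/(1-R^2_j)$, with perfect collinearity
  reported as infinite. On the balanced full factorial the VIFs are 1 by
  construction; values below 10 are conventionally unproblematic.
* **Backward elimination** at α = 0.05, one predictor per step (largest p
  first), with the trace retained. On data generated with a null baffle
  effect, elimination removes exactly `baffle` in the large majority of
  seeded repetitions (tested).

The reduced two-parameter prediction equation
$PD = \exp(b_0 + b_A \ln A + b_T T)$ with the published coefficients
(15.863, −1.7769, −0.10856) is provided as `predict_diameter()`; it is
monotone decreasing in both agitation and talc, and predictions outside the
validated 150–1200 µm range are flagged, not refused.

## 3D architecture model

Volumes are isotropic voxel grids labelled void/hyphae/spore/talc. "Solid"
means hyphae + embedded talc; spores are counted separately because the
imaging distinguishes them reliably, and whether spores should count as
solid is genuinely ambiguous — the default excludes them and a flag flips
it.

* **Radial profile:** about the unweighted solid-voxel centroid, an inner
  sphere of 50 µm and shells of 25 µm out to the furthest solid voxel;
  fraction = solid voxels / all voxels per shell. Shells are half-open and
  extended strictly past the furthest voxel so boundary voxels are binned;
  the shell-wise solid counts sum to the total solid count exactly
  (integer identity, tested).
* **Spore cores:** DBSCAN over spore-voxel coordinates with a minimum of
  100 spores per cluster. The neighbourhood radius defaults to 5 voxel
  spacings: spores inside a core sit at ~1 voxel spacing, so this keeps
  the 100-neighbour core-point criterion satisfiable even where crossing
  hyphae locally displace spores, while staying far below any plausible
  core separation. This default is a review-worthy choice, exposed as a
  parameter.
* **Classes:** nSC = 1 → class I; nSC ≥ 2 → class II; class III
  (fusion of mature pellets) is flagged heuristically — nSC ≥ 2 *and* a
  strongly anomalous shape. Two shape scores are computed: the directional
  asymmetry (furthest solid voxel per 26-sector direction bin,
  max/median) and the principal-axis elongation (square root of the
  extreme eigenvalue ratio of the solid-voxel covariance). On generated
  pellets the sector score does not separate fused constructs from
  ordinary multi-core pellets — single straggler hyphae dominate sector
  extents — while elongation separates them cleanly, so elongation (default
  threshold 2.5) is the effective discriminator and asymmetry is carried
  as evidence. The class III flag is always reported as heuristic, never
  silently folded into class II. The centre solid fraction accompanies
  every classification as consistency evidence (single-core centres dense,
  multi-core centres sparse), but it is evidence, not the classifier.
* **Skeletons:** a geometric graph input gives exact metrics (sum of edge
  lengths; tips = degree-1 nodes; branch points = degree ≥ 3). A voxel
  input is first thinned to a curve skeleton by iterative simple-point
  removal (six directional sub-iterations, endpoints preserved,
  Malandain–Bertrand simple-point test) and then read as a 26-connected
  voxel graph with adjacent junction voxels merged. "Branches" is
  ambiguous between branch points and branch segments; both are computed,
  branch points being the headline. Voxel-route metrics are validated on
  architectures the voxel size can resolve; densely packed hyphae merge
  under rasterisation, exactly as they do under real tomographic
  resolution limits.

## The synthetic generator: what it emulates, and what it does not

* **Diameter populations** are lognormal mixtures — matching the
  right-skewed, occasionally multimodal distributions of real pellet
  populations and the ln-scale modelling downstream. Component medians,
  spreads and weights are free.
* **Micrographs** render radially shaded, boundary-roughened discs
  dominating the red channel, plus sub-element speckle noise, and
  requested fractions of touching pairs and border-clipped pellets. The
  ground truth records the *rendered* geometry (mask-derived ED and
  centroid), so segmentation accuracy is measured against what was
  actually drawn. Boundary roughness (default 3 % radial amplitude, four
  low-order harmonics) makes marker detection non-trivial; it is a free
  knob, not calibrated to any measured periphery texture.
* **3D pellets** grow as geometric graphs: germ tubes emerge on the
  surface of one or more spore cores and extend in fixed-length segments
  with a radial bias, per-step branching, and directional noise; the graph
  is rasterised afterwards, so the skeleton ground truth is exact by
  construction. Spore cores are partial-occupancy sprinklings (55 % of
  core-ball voxels), not solid balls — cores are agglomerates permeated by
  hyphae. Growth heading at a *foreign* core is damped away (no outward
  thrust added), encoding the observation that multi-core pellets are
  sparse between cores while their envelope still closes round; this is
  what produces the tested anti-correlation between core count and
  centre density. Fusion constructs are two separately grown mature
  pellets whose envelopes meet at their peripheries.
* **Regression datasets** draw ln-median diameters from the loglinear
  model with configurable coefficients and ln-scale noise.

Not emulated: optics and shading physics, tomographic reconstruction
artefacts, spore agglomeration kinetics over time, dispersed mycelium, and
the absolute hyphal densities of real pellets. The last point matters for
interpretation: a real single-core pellet centre has a solid fraction
around 0.2, while the generator's scaled-down hyphal forests (tens of germ
tubes, not thousands) give centre fractions nearer 0.05. The pipeline's
tested claims about density are therefore *contrasts* (single-core centres
denser than multi-core centres; density falling with radius), not absolute
levels. Equally, passing segmentation tests on rendered discs shows the
pipeline handles touching, bordering, noisy, shading-graded particles —
not that it handles every real-world illumination artefact.

## Numerical choices and problem sizes

* All randomness flows through explicit seeds; fixed seed ⇒ bit-identical
  scenes, volumes and tables. Generators save and restore the caller's RNG
  state.
* Reconstruction uses a hybrid raster-scan + queue algorithm; tests prove
  it equal to literal iterate-dilate-and-clip on 128×128 instances, for
  both 4- and 8-connectivity.
* Watershed determinism: priority queue ordered by (priority, insertion
  order).
* Structuring elements are disks of radius N pixels; "radius" is the
  chosen reading of element size N, exposed as a parameter.
* Degenerate inputs: empty images give empty marker/pellet masks; empty
  label grids give empty record tables; a constant-response regression
  reports R² = 0; an all-void volume is an error for centroid/diameter
  operations but an empty (not erroneous) spore-cluster set.
* Test and acceptance problem sizes were chosen to exercise every claim at
  a few minutes' total runtime: 50 seeded scenes of 20 pellets
  (300–2500 µm) for segmentation recovery; 500 seeded repetitions for CI
  coverage; 50 seeded volumes at 4 µm voxels for spore-core recovery; a
  200 µm ball at 2 µm voxels for the volume-equivalent diameter check.

## Known limitations

* The class III flag is a shape heuristic tuned on the generator's own
  class-conditional score distributions; real fused pellets with
  near-spherical outlines would evade it, as they evade any shape-based
  rule.
* Modality detection with the default noise guard trades a small
  false-multimodal rate on wide, sparse populations against sensitivity to
  balanced mixtures at moderate n; both error rates are nonzero, which is
  why the flag is reported with its parameters rather than applied
  silently.
* The voxel-route skeleton under-counts tips merged by rasterisation and
  over-counts branch points where hyphae cross within a voxel; tolerances
  in the tests (10 % on length and tips, on resolvable architectures)
  reflect that.
* Replicates are modelled as independent observations in the regression;
  a hierarchical model would be the natural extension but is out of scope.
* The manual re-measurement path for unsegmentable pellets exists only as
  the `source = "manual"` record flag and CSV import; there is no
  interactive tooling.
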