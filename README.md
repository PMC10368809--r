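# mifspatial

Spatial phenotyping of multiplex immunofluorescence (mIF) tissue images and
downstream survival analysis, for studies that ask how the *composition* and
*spatial arrangement* of immune cells in the tumour microenvironment relate
to patient outcome.

The package implements the full quantitative chain used in large mIF cohort
studies of non-small cell lung cancer, where two five-marker panels are
stained on serial sections of each tumour (panel 1: FOXP3, CD38, CD4, CD20,
CD66b; panel 2: CD8, CD68, PD-L1, CD163, CD133, each with a DAPI
counterstain):

* **Nucleus detection and evaluation** — a classical detector (Gaussian
  smoothing, Otsu threshold, distance-transform watershed) on the DAPI
  channel, and evaluation of *any* segmentation against ground truth by
  one-to-one IoU matching (match iff IoU > 0.6), object-level
  F1 = 2PR/(P+R) with P = TP/(TP+FP), R = TP/(TP+FN), and binary pixel
  accuracy.
* **Per-cell marker quantification** — fluorescence fields (CF) are
  intersected with nucleus coordinates (CCN) to attribute marker signal to
  cells; mean intensities are binned against each marker's positive
  threshold Z into fluorescence-strength (FS) levels
  (< Z negative, [Z, 2Z) low, [2Z, 3Z) median, ≥ 3Z high); marker intensity
  over a cell population is summarized by the H-score
  `H = %low x 1 + %median x 2 + %high x 3` ∈ [0, 300].
* **Phenotype and compartment calls** — ordered marker rules (e.g.
  CD4+FOXP3+ → Treg before CD4+ → CD4 T), and tumour-nest (TN) vs
  tumour-stroma (TS) assignment from a compartment mask.
* **Spatial features** — the Delaunay triangulation of each section's cell
  centroids defines cell adjacency; for each panel all C(5,2) + 5 = 15
  unordered class pairs (30 over two panels) get the mean Delaunay edge
  length in microns between the paired classes, averaged across a patient's
  sections.
* **Composition features** — per compartment: class percentages (%/sight),
  densities (cells/mm²), marker H-scores and the Treg/CD4 T ratio; 66
  content features by default.
* **Survival statistics** — multivariate Cox (Efron ties) via the survival
  package, Kaplan–Meier/log-rank, outcome-based optimal cutoffs maximizing
  the log-rank χ² (X-tile criterion, with an optional permutation
  correction), and inverse-variance fixed-effects pooling of stratum log
  hazard ratios: pooled θ = Σwᵢθᵢ/Σwᵢ with wᵢ = 1/SEᵢ².
* **Six-gene risk score** — the frozen neutrophil differentiation
  expression gene score
  `NDEGS = 0.706 CTSZ + 1.225 PLAUR + 1.268 NME2 + 1.339 NPM1 + 1.349 EIF3E + 1.555 PPIA`,
  with 7:3 train/validation splitting, cutoff learned on training only,
  IPCW time-dependent AUC at 1/3/5 years, and tumour mutational burden
  classification (TMB-high at ≥ 20 mut/Mb).

Because raw mIF cohorts of this kind are rarely shareable, a first-class
**synthetic-data module** generates scenes with known ground truth:
tumour-nest/stroma geometry, hard-core Gibbs point-process cell placement
with pairwise phenotype attraction/repulsion, star-convex eight-ray nuclei,
phenotype-conditioned lognormal marker intensities, stage-dependent
composition shifts, and Weibull proportional-hazards outcomes. Every stage
of the pipeline is tested against this generator's ground truth.

## Worked example

```r
library(mifspatial)

spec  <- sceneSpec(nCells = 300, seed = 1)      # 1024 x 768 px @ 0.5 um/px
scene <- generateScene(spec)
scene
#> MifScene: 1024 x 768 px @ 0.50 um/px
#>   panel 1: 300 cells, 6 channel(s)
#>   panel 2: 300 cells, 6 channel(s)

Z     <- setNames(rep(1, 10), unlist(panelMarkers()))  # true thresholds
cells <- quantifyScene(scene, thresholds = Z)

v <- sectionSpatialFeatures(cells)
round(v[c("p1.CD4_T.vs.neutrophil", "p2.CD8_T.vs.macrophage")], 1)
#> p1.CD4_T.vs.neutrophil p2.CD8_T.vs.macrophage
#>                   26.1                   23.6
```

The CD4 T–neutrophil entry says that Delaunay-adjacent CD4 T cells and
neutrophils on panel 1 sit 26.1 µm apart on average in this section —
shorter distances indicate closer interplay between the two populations.

```r
feats <- sectionContentFeatures(cells, compartmentMask(scene), pixelSize(scene))
round(feats[c("pct_neutrophil_TS", "dens_CD8_T_TN")], 2)
#> pct_neutrophil_TS     dens_CD8_T_TN
#>              3.30             73.67
```

3.3% of stromal panel-1 cells are CD66b+ neutrophils; intratumoural CD8 T
cells run at 74 cells/mm². Pooling the prognostic effect of a population
across its FS strata:

```r
pool <- fixedEffectsPool(c(-0.027, -0.011, 0.004), c(0.008, 0.006, 0.01))
#> pooled HR 0.987 (95% CI 0.979-0.996), p = 0.003
```

and evaluating the six-gene score on a synthetic expression cohort with a
planted hazard link:

```r
e  <- generateExpression(500, scoreEffect = 1, seed = 7)
ev <- splitAndEvaluate(ndegsScore(e), e$time, e$event, seed = 7)
round(ev$auc, 3)
#>  t365 t1095 t1825
#> 0.893 0.829 0.807
```

A thin command-line front end over these functions is provided in
`inst/scripts/mifspatial.R` (subcommands `simulate`, `segment`, `ndegs`).

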