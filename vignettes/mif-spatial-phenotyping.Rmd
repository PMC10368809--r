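---
title: "Methods: spatial phenotyping of multiplex immunofluorescence cohorts"
author: "mifspatial authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phenotyping of multiplex immunofluorescence cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifspatial)
```

# The analysis problem

Multiplex immunofluorescence (mIF) stains a handful of protein markers plus
a DAPI nuclear counterstain on one tissue section, so that every cell can be
assigned a marker profile *and* a position. In tumour cohorts this supports
two families of patient-level features: *composition* (how much of each
immune population is present, and where — tumour nest vs stroma) and
*spatial arrangement* (how close population A sits to population B). Both
families are then tested against survival. `mifspatial` implements that
chain end to end for the two-panel, ten-marker design: panel 1 carries
FOXP3, CD38, CD4, CD20 and CD66b; panel 2 carries CD8, CD68, PD-L1, CD163
and CD133. Each panel is stained on its own 4 µm serial section, which has a
consequence the package enforces throughout: the two panels share tissue
geometry but *not* cell coordinates, so spatial pairs are only ever formed
within a panel, never across panels.

# Per-cell quantification

**Fields and nuclei.** Marker signal is attributed to cells by intersecting
the fluorescence field of a channel (pixels above a background quantile,
default 0.95) with the nucleus coordinates. Each nucleus is dilated by
`dilationPx` pixels (default 2, about 1 µm at the default 0.5 µm/px) so that
membrane and cytoplasmic staining adjacent to the nucleus is captured;
dilated zones grow competitively so a contested pixel joins the nearer
nucleus. Field pixels outside every dilated nucleus are discarded as
non-specific signal. A cell's marker intensity is the mean over its
attributed field pixels (0 if none).

**FS levels and the H-score.** Each marker has a positive threshold `Z` in
the channel's intensity units. In the study design this threshold is set
visually by pathologists, so for real data it is a required input
(`thresholds` argument, JSON via `readThresholds()`); when absent the
package falls back to an Otsu threshold on the per-cell intensity
distribution and says so. Mean intensities bin into fluorescence-strength
levels at Z, 2Z and 3Z. The paper-of-record convention leaves the boundary
side unstated; we take bins closed below (an intensity of exactly 2Z is
"median"). The H-score summarizes a marker over a cell population as
`%low x 1 + %median x 2 + %high x 3` on the 0–100 percentage scale, hence a
0–300 range — the standard H-score convention.

**Phenotypes.** Cells are phenotyped by an ordered rule table (first match
wins): panel 1 — CD4+FOXP3+ regulatory T cell, CD4+ helper T cell, CD38+
activated T cell, CD20+ B cell, CD66b+ neutrophil; panel 2 — CD68+CD163+
M2 macrophage, CD68+ macrophage, CD8+ cytotoxic T cell, CD133+ cancer stem
cell. "Positive" means any FS level above negative. PD-L1 is biologically a
state rather than a lineage, so it is recorded as an independent per-cell
flag; cells matching no panel-2 lineage rule but PD-L1-positive are
labelled `PDL1_pos`, which also gives the spatial schema its fifth panel-2
class. The full marker-to-type table of the original study is not public;
this rule table is a documented reconstruction and is fully replaceable via
`phenotypeRules()`.

# Spatial features

Cell adjacency is the Delaunay triangulation of a section's cell centroids
(via `deldir`), and the spatial feature for an unordered class pair {A, B}
is the arithmetic mean length (µm) of Delaunay edges joining an A cell to a
B cell (both ends A when A = B). The source convention names the connection
length but not the aggregation; the mean is the default and a median is
available (`agg = "median"`). Only Delaunay-adjacent pairs contribute — the
triangulation defines "connection" — and a pair with no qualifying edge is
missing, never zero. Per panel the five classes give C(5,2) + 5 = 15 pairs,
30 over both panels; when a patient has several sections, each feature is
averaged over the sections where it is defined. Features are computed over
the whole image by default; per-high-power-field computation is a matter of
slicing the cell table before calling `sectionSpatialFeatures()`.

Degenerate inputs are handled explicitly: duplicate centroids are
deduplicated with a warning, and fewer than three (or collinear) points
yield an edgeless graph with a warning rather than an error, so sparse
sections degrade to missing features. Cocircular point sets (e.g. a perfect
square) are resolved by the triangulator's tie-break; the brute-force
empty-circumcircle oracle in the test suite pins the behaviour on small
general-position sets.

# Composition features

Per compartment (tumour nest TN / tumour stroma TS, taken from a
compartment mask; the machine-learned tissue segmentation of the original
workflow is replaced by mask ingestion): class percentages (%/sight, with
the class's own panel as denominator), densities in cells/mm² (counts over
the compartment's pixel area times the pixel size squared), marker H-scores
over the compartment's cells, and ratio features (default: Treg over CD4 T
percentage, per compartment). The published pipeline reports 66 content
features without listing them; the package's default schema reaches that
count as 11 classes x 2 compartments x {percentage, density} (44) + 10
markers x 2 compartments H-scores (20) + the Treg/CD4 T ratio x 2 (2). The
11th class is `other` (cells matching no rule), which exists on both serial
sections and is therefore pooled across panels (its density averages the
two sections). The schema is configurable and the emitted count is
reported, so alternative decompositions are a parameter choice, not a code
change. Missing values are written as empty CSV fields and never imputed
with zeros.

# Survival statistics

Cox models delegate to `survival::coxph` with Efron tie handling (the
source does not state its handling; Efron is the accurate default). The
outcome-based optimal cutoff maximizes the two-group log-rank chi-square
over candidate cutoffs at observed feature values, subject to both groups
holding at least `minGroupFrac` (default 0.1) of the cohort; ties take the
lower cutoff for determinism, and membership in the high group is strictly
`value > cutoff`. Because maximal selection inflates the naive log-rank
p-value, `xtileCutoff()` optionally reports a permutation-adjusted p
(`nPerm` label permutations); the raw p is always reported too, since that
is what the original analyses quote. The X-tile program's internal
Miller–Siegmund correction is not reproduced. Fixed-effects pooling of
stratum effects is plain inverse-variance weighting on the log hazard-ratio
scale; the intended strata are the fluorescence-strength levels of one
population/compartment, but the function accepts any `(theta, se)` set and
the test suite cross-checks it against `metafor::rma(method = "FE")`. No
multiple-testing correction is applied across feature–outcome tests by
default, matching the source analyses; `p.adjust` composes trivially if
wanted.

# The six-gene risk score

The neutrophil differentiation expression gene score is a frozen linear
combination (coefficients in `ndegsCoefficients()`); the LASSO selection
that produced it is intentionally *not* re-run — the printed coefficients
are the deliverable. The coefficients are bound to the expression scale
they were fitted on, which the source does not specify; callers must
therefore supply expression on one consistent, documented normalization and
treat scores as comparable only within it. Cohort evaluation splits 7:3,
learns the cutoff on the training split only, and applies it unchanged to
validation (the conservative reading of an unstated choice). The
time-dependent AUC is the IPCW cumulative/dynamic estimator (cases: events
by t, weighted by the inverse Kaplan–Meier censoring survival; controls:
subjects beyond t; score ties count a half); it is validated against an
independent implementation on a fixed synthetic fixture. TMB is mutations
per interrogated megabase (default 38 Mb, a whole-exome convention) with
the TMB-high boundary at 20 mut/Mb taken inclusively — the boundary side is
another unstated detail, decided here and documented.

# The synthetic-data generator

The generator exists so that every stage has ground truth. One scene is:

* **Geometry** — a non-tissue border (3% of the shorter side), tumour-nest
  blobs (default 5, radii 40–90 µm) inside the tissue rectangle, stroma
  elsewhere. Default raster 1024 x 768 px at 0.5 µm/px (fast enough for
  whole-pipeline simulations); `fullRes = TRUE` gives the 4028 x 3012
  full-slide geometry.
* **Cells** — phenotypes drawn from an 11-class mixture
  (`defaultMixture()`); positions from a hard-core dart process (hard core
  = mean nucleus diameter, 7 µm) refined by 2000 Metropolis sweeps under a
  pairwise Gibbs potential: interaction strength s(A,B) lowers the energy
  of each A–B pair within 30 µm, so s > 0 is attraction, s < 0 repulsion.
  The kernel is compiled (Rcpp) and uses R's RNG, so scenes are
  bit-reproducible under a seed. An infeasible packing fails with the
  density named.
* **Nuclei** — star-convex eight-ray polygons, base radius 3.5 µm, ray
  radii jittered ±30%; contested pixels go to the nearer centroid so
  ground-truth nuclei are pairwise disjoint.
* **Intensities** — positive markers render a lognormal draw around a
  representative level multiple of Z (1.5Z / 2.5Z / 3.6Z for low/median/
  high), then Gaussian blur and background noise. Setting the lognormal
  spread, blur and noise to zero yields noiseless scenes where
  quantification must recover the truth exactly — the basis of the
  end-to-end recovery checks. The staining-intensity distribution of real
  mIF is not quantified in the source; the lognormal model is a declared
  assumption, not an inference.
* **Serial sections** — both panels share the compartment mask but
  re-place cells independently, mirroring the physics of serial sections.

A cohort adds stage groups (prevalences 383:170 early vs mid-to-late),
stage-dependent composition shifts (defaults: neutrophils −3 pp, CSC
−1.5 pp, M2 macrophages +3 pp in the mid-to-late group, balanced against
`other` — echoing the progression pattern the pipeline is meant to
detect), clinical covariates, and Weibull(shape 1.2, scale 2000 days)
proportional-hazards outcomes with mixed uniform-random plus administrative
censoring. Because scene rendering is expensive at simulation scale,
`generateCohort(makeScenes = FALSE)` draws each patient's true composition
directly from the same stage-adjusted multinomial the scenes realize; the
rendered path (`makeScenes = TRUE`) is used when rasters are needed.

What the generator does **not** emulate: optics (point-spread functions,
autofluorescence, spectral unmixing), marker co-expression beyond the rule
table, cell-shape diversity, tissue artefacts, or spatially varying
staining. Tests passing on synthetic data therefore establish the
*computational* correctness of the chain — quantification recovers planted
truth, spatial features detect planted interactions, survival statistics
recover planted coefficients — not the biological validity of any threshold
or rule table on real slides.

One deliberate deviation in the validation design: at zero interaction
strength cell positions still follow a *hard-core* process, so comparing
cross-phenotype spacing against a literal complete-spatial-randomness
envelope would be biased at short range (the hard core is of the same order
as the mean nearest-neighbour spacing at test densities). The zero-strength
check instead uses the random-labelling envelope — 200 permutations of the
phenotype labels on the fixed point pattern — which is exactly the
component that "no interaction between phenotypes" asserts.

# Problem sizes and numerical choices

The shipped test and acceptance runs use: 500-cell scenes for noiseless
recovery; 150-cell scenes, 10 seeds per arm, for the planted-attraction
comparison (one-sided rank test); cohorts of n = 1000 without rendering,
10 seeds per coefficient in {0, 0.25, 0.5}, for Cox recovery; 30–50 seeds
of n = 300 expression cohorts for the null calibration of the validation
AUC. These sizes were chosen so the whole suite runs comfortably on a
laptop while keeping Monte-Carlo error well inside the asserted
tolerances. Other numerical choices: strict IoU inequality (> 0.6) for
object matching with greedy descending-IoU one-to-one assignment (checked
against brute-force optimal assignment on small scenes); precision defined
as 0 with a warning when nothing is predicted; IoU of two empty sets is an
error, not a value; label masks are relabelled to contiguous ids before
comparison; channel TIFFs store intensities scaled by a declared full-scale
constant (default 16) because TIFF pages hold unit-range samples.

# Known limitations

* The phenotype rule table and the 66-feature decomposition are
  reconstructions of partially unpublished choices; both are configurable.
* Marker thresholds Z on real data are pathologist-set inputs; the Otsu
  fallback is a convenience, not a substitute for expert calibration.
* The classical nucleus detector is a baseline; the evaluation half of the
  segmentation module is detector-agnostic and is the part meant for
  production use.
* Cross-panel spatial relationships are out of reach by design (serial
  sections), as are k-nearest-neighbour graphs and neighbourhood-
  composition clustering.
* The risk-score coefficients are scale-bound; applying them to expression
  on a different normalization than they were fitted on yields scores whose
  *ranking* may survive but whose cutoffs do not.
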