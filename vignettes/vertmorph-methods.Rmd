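---
title: "Vertebral morphometry with vertmorph: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebral morphometry with vertmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertmorph)
```

# Scope

`vertmorph` measures anterior, posterior and central vertebral body heights
(Ha, Hp, Hc) on midsagittal sections of labeled spine segmentation masks and
provides the cohort statistics built on those heights: sex-stratified
reference tables, wedge (Ha/Hp) and biconcavity (Hc/Hp) indices, pooled
t-tests with power analysis, ICC(2,k) reader agreement, a cubic
truncated-power spline mixed model of height on vertebral level, and
intra-individual height-ratio (Pseudo-Jacobian) matrices. Thoracolumbar
levels T1–L5 are coded 1–17 cranio-caudally throughout. Deep-learning
segmentation itself, DICOM handling and visual quality control are out of
scope; the pipeline starts from masks and represents QC only as an
error-taxonomy exclusion tally.

# Coordinate and pixel conventions

All 2D operations use (row, col) indices with rows increasing caudally
(superior to inferior) and columns increasing posteriorly; the
`anteriorLow` flag flips the anterior/posterior reading for mirrored data.
Pixel spacing is carried per axis in mm and every distance is computed on
mm-scaled displacements, so anisotropic slices are supported; CT slices are
rarely isotropic and the measurement should not depend on the storage grid.

The synthetic rasterizer declares a pixel foreground iff its center lies
inside the continuous shape, with boundary points counted as inside, and
anchors the shape so that its bounding-box corner falls on a pixel center.
The inclusive rule is what makes exactness on axis-aligned rectangles
attainable: a 20 mm edge must span pixel centers 20 mm apart, i.e. 21
boundary-inclusive pixels at 1 mm spacing. These conventions fix the ground
truth unambiguously and are asserted by tests.

# The landmark algorithm

For each vertebra label the midsagittal slice is taken at the rounded
sagittal coordinate of the centroid of the union of the (up to) two largest
3D connected components of that label — the vertebral body and the
posterior process. Six-connectivity is used in 3D; in 2D, foreground
components follow the standard 8-connected foreground / 4-connected
background duality of the contour tracer.

**Posterior-element removal.** Whole-vertebra labels include the pedicles
and spinous process, which must not influence the body contour. If the
foreground is already disjoint, the most anterior component holding at
least 25% of the foreground area is kept. Otherwise a morphological opening
with increasing disc radius (cap 10 pixels; both parameters are arguments)
is applied until the foreground splits. A split is accepted as a
body/process separation only if it detaches a component *below* the 25%
area floor; when the opening instead cuts the body itself in two
comparably-sized halves — which happens on strongly biconcave bodies with a
thin waist — nothing process-like was found and the input is returned
unchanged. After an accepted split the kept component's boundary is
restored by a single conditional dilation with the same structuring
element, clipped to the original mask. A full geodesic reconstruction would
be pointless here: body and process are connected through the bridge, so
reconstruction-to-stability would regrow everything that was just removed;
the one-step conditional dilation restores exactly the shell the opening's
erosion took away while regrowing at most one radius into the bridge.

**Four-vertex contour approximation.** The outer contour of the body is
simplified by recursive farthest-point (Ramer–Douglas–Peucker)
simplification of the closed curve, anchored at the two most distant
contour points. The tolerance is not a free parameter: it is binary-searched
to the smallest value that yields exactly four vertices (ties resolved
toward the smaller tolerance), since the vertex count — not the tolerance —
is the specification of the step. Simplification distances are computed in
mm so that anisotropic spacing does not distort corner angles.

Two refinements sharpen the corner estimate beyond raw RDP output, both
enabled by default and both reducible (`subpixel = FALSE` gives plain
contour pixels):

* the four vertices are moved to the contour pixels maximizing the
  inscribed quadrilateral area (coordinate descent, seeded by the RDP
  solution) — RDP picks *a* point on each corner arc, the maximum-area quad
  picks the extreme one;
* each corner is then refined to the intersection of robust
  total-least-squares line fits of its two adjacent contour edges. Each
  edge is fitted on its outer quarters only (the middle may hold an
  endplate concavity, the ends are rounded by rasterization), outliers are
  trimmed by MAD, and the fitted line is repositioned as a support line
  through its outermost inlier. Support positioning is the debiasing step:
  mask pixel centers lie up to one pixel *inside* the continuous edge, so a
  least-squares line through them is systematically half a pixel inward,
  while the outermost pixel is nearly unbiased — and exactly on the edge
  whenever the edge runs through pixel centers, which preserves exactness
  on rectangles. Per corner, the farther-out of the pixel vertex and the
  line-intersection vertex is kept, since each is the accurate one in the
  regime where the other is biased.

**Corner labeling.** The four vertices, taken in cyclic order, are assigned
to AS/PS/AI/PI by maximizing the combined "superior above inferior" plus
"anterior in front of posterior" margin over the eight cyclic assignments.
For un-rotated bodies this reduces to the simple rule (two lowest rows are
superior; lower column is anterior under the default orientation), but it
remains correct for rotated vertebrae where the row ranking of a posterior
superior and an anterior inferior corner can swap.

**Central landmarks.** The superior and inferior endplate midpoints are the
half-up-rounded means of the corresponding corner pairs (Bresenham requires
integer endpoints). The segment between them is rasterized with Bresenham's
algorithm and walked from each end; the first foreground pixel from the
superior end is CS, from the inferior end CI. On a convex body the
midpoints themselves are on the mask; on a biconcave body the landmarks
move inward past the concavity, which is precisely what makes Hc a central
height. The walk is restricted to the midpoint segment; walking the full
endplate column would be the alternative reading, and would differ only
when the deepest concavity point is laterally displaced from the midpoint
column.

Heights are then plain Euclidean norms of the mm-scaled landmark
displacements. Scaling before the norm (rather than measuring in pixels and
converting after) is the only order compatible with anisotropic spacing.

## Accuracy

On axis-aligned rectangles the extracted heights equal truth exactly. On
randomly generated bodies (rotations up to ±20°, endplate concavities up to
20% of body height, anisotropic spacings 0.5–1.5 mm) the extracted heights
lie within 2 × max(spacing) of the continuous truth; the package's
benchmark runs 100 such shapes per suite, and the residual error is
dominated by the integer-pixel quantization of the central landmarks, which
the specification of the walk fixes by design.

# The synthetic-data generator

`makeVertebraMask` rasterizes a simple quadrilateral with circular-segment
endplate concavities: the bite is centered at the edge midpoint, entered
along the midline direction with a prescribed central depth, and its chord
spans half the edge — the simplest shape with a controllable central depth
that reproduces a biconcave silhouette. By construction the true central
height is the distance between the endplate midpoints minus the two depths.
Boundary noise, when requested, is applied as independent normal jitter of
a densely sampled contour before rasterization (not pixel flipping), so the
truth landmarks stay well defined. `makeSpineVolume` extrudes each body
over several sagittal slices and attaches a smaller posterior disc through
a 2-pixel bridge, mimicking the connected whole-vertebra labels produced by
segmentation tools.

`makeHeightCohort` draws, per subject, a random intercept `b0 ~ N(0, 2²)`
and slope `b1 ~ N(0, 0.1²)` (shared across the three height types — a
subject is one skeleton) and adds independent residuals
`ε ~ N(0, 1.5²)` per record and type around a per-level, per-sex mean
curve. The default cohort has 262 subjects with 129 males, matching the
reference study conditions. The default mean curve treats the published
sex-specific mean height table as the posterior height Hp and derives
Ha and Hc by multiplying with the published cohort-mean wedge and
biconcavity indices; the source table does not state which height type its
means describe, and anchoring Hp makes the index scaling exact by
construction. The SDs (2 mm between subjects, 0.1 mm/level slope, 1.5 mm
residual) are plausible for adult vertebral heights whose cohort SDs are a
few millimetres; they are stated here because the source tables print no
dispersion to copy.

What the generator does **not** emulate: CT physics (no intensities, noise
textures, partial-volume effects), scanner or protocol differences,
pathology (fractures, degenerations), or age structure. Passing tests on
synthetic data therefore demonstrate the correctness of the geometry and
statistics, not segmentation robustness on real scanners.

# Statistical machinery

**Sex deltas.** Per-level male and female means with absolute
(male − female, 2 decimals) and relative differences (percent of the male
mean, 1 decimal). The male-mean denominator is the reading that reproduces
the published percentages from the published means; report rounding
(heights 2 dp, percents 1 dp, indices 2 dp) is centralized to match the
reference tables.

**Indices.** Wedge and biconcavity indices are computed per record; group
means are means of per-subject ratios, not ratios of means.

**Tests.** The sex comparison is a pooled-variance (Student) two-sample
t-test by default — Welch's correction is an argument — and the power of
the two-sided test is computed from the noncentral t distribution with
noncentrality `d·sqrt(n1·n2/(n1+n2))`, two-sided α = 0.05 by default.
No multiple-testing correction is applied, matching the reference analysis.

**ICC(2,k).** Two-way random effects, absolute agreement, average measures,
computed from the ANOVA mean squares:
`(MSR − MSE) / (MSR + (MSC − MSE)/n)`. The implementation is cross-checked
against an independent `aov`-based computation to 10⁻¹⁰ in the tests.

**Mixed spline.** The mean structure is the truncated-power cubic basis
`1, ver, ver², ver³, (ver−9)³₊, (ver−13)³₊` plus a male indicator; the
truncated terms vanish at and below their knots, so the mean function has
continuous first and second derivatives everywhere. Random effects are a
correlated per-subject intercept and slope in `ver` (unstructured 2×2
covariance); on a failed correlated fit the model falls back to independent
effects, flagged in the result. Estimation is maximum likelihood by
default — not REML — so that AIC/BIC comparisons across fixed-effect
structures (cubic vs linear spline vs ordinary least squares) are valid;
REML is available for variance reporting. `AIC = −2·logLik + 2p` and
`BIC = −2·logLik + p·log(n_obs)` are computed from the ML log-likelihood
with p taken from the fitted object's degrees of freedom. Marginal and
conditional R² follow the variance-decomposition definition: the fixed
variance is the variance of the fixed-effect predictor, the random variance
is the mean of `τ00 + 2τ01·ver + τ11·ver²` over the observations, and the
denominators add the residual variance. Sex-stratified fits are the same
model without the sex indicator run per sex; knots stay at (9, 13) in
stratified fits rather than being re-searched, keeping the models
comparable across sexes. `knotSearch` fits every candidate knot set and
ranks by AIC; the empty set (knot-free cubic) is a valid candidate.

**Ratio matrices.** For one subject, `J[i,j] = H_i/H_j` with the row as
numerator, so sub-diagonal entries are caudal-over-cranial ratios — the
orientation consistent with adjacent-level ratios slightly above 1 through
the thoracolumbar junction. The diagonal is exactly 1, reciprocal
antisymmetry `J[i,j]·J[j,i] = 1` and transitivity `J[i,j]·J[j,k] = J[i,k]`
hold per subject to machine precision, and the matrix is invariant to
rescaling all of a subject's heights. Cohort matrices are element-wise
means over subjects, for which reciprocal antisymmetry deliberately does
*not* hold (the mean of reciprocals is not the reciprocal of the mean); a
test documents the distinction. The 3×3 regional reduction averages cells
over T1–T9, T10–L1 and L2–L5 row/column blocks, matching the spline
segments. For the sex comparison each subject is summarized by the mean of
their ratio-matrix row for the level (or region) in question, diagonal
excluded — one row per level requires some scalarization and the row mean
is the simplest symmetric choice — and groups are compared with Welch's
t-test by default (signed statistic; a rank-sum variant with normal
approximation is available). The identity of the signed "W-statistic"
printed in the reference tables is not stated there; both candidates are
provided and neither is claimed to match.

# Numerical choices and degenerate inputs

Midpoint rounding is half-up on both axes (banker's rounding would make
midpoint pixels parity-dependent). The RDP tolerance search runs 60
bisection steps with a downward scan fallback for the rare non-monotone
jump past four vertices; a contour that never yields four vertices (e.g. a
one-pixel line) raises an approximation-failure error. Degenerate
quadrilaterals (duplicate or collinear vertices) are rejected at corner
labeling; an empty Bresenham walk raises a central-landmark failure; zero
landmark distances raise a degenerate-landmark error; missing labels and
empty centroid slices raise their own errors. All of these surface in the
pipeline as logged exclusions rather than aborting a cohort run, echoing a
manual QC step as an automated tally (a semantic difference from visual
review that users should keep in mind). Cohort generation validates
non-negative SDs; the ICC is undefined on constant matrices; model
comparison refuses fits whose data checksums differ.

# Problem sizes in the test suite

The suite exercises the landmark chain on 100 random bodies per run,
parameter recovery on 100 simulated cohorts of 262 subjects (20 inside the
module tests), knot selection on 50 cohorts against three neighboring
candidate sets, 200 cohort replicates for the per-level significance
pattern and 100 for the lumbar-wedge detection rate, and 2000 subjects for
variance-component convergence. These sizes give Monte-Carlo rates stable
enough for the asserted thresholds while keeping a full run in the order of
a few minutes.

# Known limitations

* The landmark algorithm is pixel-based at its core; central heights
  inherit up to roughly one pixel of quantization from the Bresenham walk,
  and coarse-resolution slices (≥ 1.5 mm) of small vertebrae carry
  correspondingly larger relative error.
* The posterior-element removal is a heuristic tuned to body-plus-process
  topology; exotic missegmentations (e.g. two vertebrae under one label)
  are not detected beyond the generic error taxonomy.
* Real-data results of the reference study (its mean heights, p-values,
  ICC range, supplementary coefficients) depend on a restricted dataset and
  are not reproduced; the package validates the machinery on synthetic
  cohorts with known truth instead.
* The corner-labeling margin rule assumes the body is wider than it is
  rotated; beyond roughly ±30° of in-plane rotation assignments may flip.
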