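# vertmorph

Automated vertebral body morphometry from CT segmentation masks, in R.

## The problem

Vertebral body heights — anterior (Ha), posterior (Hp) and central (Hc) —
are the raw material of spinal morphometry: they define the anterior wedge
index (Ha/Hp) and biconcavity index (Hc/Hp) used in osteoporotic fracture
grading, feed sex-specific reference curves for the thoracolumbar spine
(T1–L5, coded 1–17 cranio-caudally), and support intra-individual height
comparisons between vertebrae. Measuring them by hand is slow and
reader-dependent; this package implements an automated measurement chain
that starts from labeled segmentation masks (e.g. deep-learning whole-spine
segmentations) and ends at cohort-level statistics.

The package has two halves:

1. **Height extraction** (`extractMidsagittalSlice`,
   `removePosteriorElements`, `binarize`, `approximateQuadrilateral`,
   `labelCorners`, `centralLandmarks`, `computeHeights`, `extractHeights`):
   for each labeled vertebra the midsagittal slice is taken at the centroid
   of the two largest connected components (body + posterior process), the
   posterior elements are removed by a morphological opening heuristic, the
   body contour is simplified to exactly four vertices
   (Ramer–Douglas–Peucker with a binary-searched tolerance), the corners are
   labeled anatomically, and the central endplate landmarks are found by
   walking the Bresenham segment between the rounded endplate midpoints to
   the first mask pixel from either end. Heights are Euclidean distances
   with per-axis mm scaling:

   `Ha = ‖AS − AI‖, Hp = ‖PS − PI‖, Hc = ‖CS − CI‖`.

2. **Cohort statistics** (`sexDeltaTable`, `wedgeBiconcavity`,
   `perLevelTest`, `powerTwoSample`, `icc2k`, `segmentMeanSlope`,
   `fitMixedSpline`, `fitLinearSpline`, `knotSearch`, `compareModels`,
   `subjectRatioMatrix`, `cohortMeanMatrix`, `regionalMatrix`,
   `ratioSexTest`): sex-stratified tables and pooled t-tests, ICC(2,k)
   reader agreement, the cubic truncated-power spline mixed model

   `height_ij = β0 + b0i + (β1 + b1i)·ver_ij + β2·ver²_ij + β3·ver³_ij +
   β4·(ver_ij − 9)³₊ + β5·(ver_ij − 13)³₊ + β11·I(male) + ε_ij`

   with per-subject random intercept and slope and knots at T9/L1, and the
   intra-individual N×N height-ratio ("Pseudo-Jacobian") matrices
   `J[i,j] = H_i / H_j` with their 3×3 regional reduction over T1–T9,
   T10–L1 and L2–L5.

A synthetic-data module (`makeVertebraMask`, `makeSpineVolume`,
`makeHeightCohort`) generates masks with exact continuous-space landmark
ground truth and height cohorts with known generative parameters, so the
whole pipeline is testable end to end without patient data.

## Worked example

```r
library(vertmorph)

# a biconcave vertebra-like body: 20 mm anterior, 19 mm posterior edge,
# 1.5 mm deep endplate concavities, rasterized at 1 mm
spec <- vertebraShape(20, 19, 30,
                      concavitySuperior = 1.5, concavityInferior = 1.5)
res  <- makeVertebraMask(spec, seed = 1)
trueHeights(res$truth)
#>   Ha   Hp   Hc
#> 20.0 19.0 16.5

body <- removePosteriorElements(binarize(res$mask))
extractHeights(body)$heights
#>  Ha  Hp  Hc
#>  20  18  16
```

The extracted heights sit within the pixel-level tolerance (2 × spacing) of
the continuous truth; on axis-aligned rectangles they are exact.

```r
# a synthetic 262-subject cohort at the package's reference conditions
coh <- makeHeightCohort(cohortSpec(seed = 1))$records
head(sexDeltaTable(coh, "Hp"), 3)
#>   level label male_mean female_mean delta_mm delta_pct
#> 1     1    T1  15.84827    14.22599     1.62      10.2
#> 2     2    T2  17.44473    15.24787     2.20      12.6
#> 3     3    T3  17.73548    15.82794     1.91      10.8

fit <- fitMixedSpline(coh, "Hp")     # knots at T9 (9) and L1 (13)
round(r2Nakagawa(fit), 3)
#>    R2marginal R2conditional
#>         0.704         0.903
```

The delta table mirrors the published male–female differences (largest in
the upper thorax, smallest in the lumbar spine); the marginal/conditional
R² split shows how much of the height variance the level-and-sex fixed
effects explain versus fixed plus per-subject random effects.

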