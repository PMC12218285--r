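# Shared fixtures: random body specs, independent oracles, tiny cohorts.

# Draw one random vertebra-like MaskSpec under the benchmark conditions:
# rotations up to +/-20 deg, concavities up to 20% of height, anisotropic
# spacing 0.5-1.5 mm. Uses the current RNG stream.
randomBodySpec <- function() {
  hA <- runif(1, 14, 28)
  hP <- hA * runif(1, 0.85, 1.15)
  w <- runif(1, 25, 35)
  cmax <- 0.2 * min(hA, hP)
  vertebraShape(hA, hP, w,
                concavitySuperior = runif(1, 0, cmax),
                concavityInferior = runif(1, 0, cmax),
                rotation = runif(1, -20, 20),
                spacing = runif(2, 0.5, 1.5))
}

# Full canonical extraction chain on a generated mask.
chainHeights <- function(res) {
  body <- removePosteriorElements(binarize(res$mask))
  extractHeights(body)$heights
}

# Independent point-in-polygon oracle (ray casting, even-odd rule with
# inclusive boundary) used to cross-check the rasterizer.
oracleInPolygon <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-boundary?
    d <- {
      ab <- c(xj - xi, yj - yi)
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else
        max(0, min(1, ((px - xi) * ab[1] + (py - yi) * ab[2]) / len2))
      sqrt((px - (xi + t * ab[1]))^2 + (py - (yi + t * ab[2]))^2)
    }
    if (d <= tol) return(TRUE)
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# Two-subject cohort whose heights equal the published sex-specific means
# (all height types set to the posterior-height reference curve).
referenceTwoSubjectCohort <- function() {
  ref <- vertebraReferenceMeans()
  arr <- defaultMeanCurve()
  for (type in c("Ha", "Hp", "Hc")) {
    arr[, "male", type] <- ref$male_mean
    arr[, "female", type] <- ref$female_mean
  }
  makeHeightCohort(cohortSpec(nSubjects = 2, sexRatio = 0.5, meanCurve = arr,
                              sdIntercept = 0, sdSlope = 0, sdResidual = 0,
                              seed = 1))$records
}

# Spline coefficients obtained by projecting the default male posterior
# height curve onto the (9, 13) truncated-power basis: the study-like
# S-curve used as simulation truth.
referenceSplineBeta <- function(knots = c(9, 13)) {
  lv <- 1:17
  X <- cbind(1, lv, lv^2, lv^3)
  for (k in knots) X <- cbind(X, pmax(lv - k, 0)^3)
  beta <- qr.solve(X, defaultMeanCurve()[, "male", "Hp"])
  names(beta) <- c("(Intercept)", "ver", "ver2", "ver3",
                   if (length(knots)) paste0("tp", knots))
  beta
}
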