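#' Vertebral level codes
#'
#' The 17 thoracolumbar levels T1..T12, L1..L5, coded 1..17 cranio-caudally.
#'
#' @return character vector of level labels in level order.
#' @export
levelLabels <- function() c(paste0("T", 1:12), paste0("L", 1:5))

#' Published sex-specific mean vertebral heights
#'
#' Reference mean vertebral body heights (mm) for males and females at
#' T1..L5, as reported for a 262-subject adult CT cohort, together with the
#' absolute (mm, 2 dp) and relative (%, 1 dp, male denominator) sex
#' differences recomputed from the means.
#'
#' @return data.frame with columns \code{level}, \code{label},
#'   \code{male_mean}, \code{female_mean}, \code{delta_mm},
#'   \code{delta_pct}.
#' @export
vertebraReferenceMeans <- function() {
  male <- c(15.69, 17.11, 17.44, 18.28, 19.14, 19.49, 19.38, 19.22, 20.47,
            22.13, 23.24, 24.94, 26.84, 27.26, 27.62, 27.13, 26.13)
  female <- c(14.35, 15.56, 16.01, 16.83, 17.61, 17.89, 17.91, 18.01, 18.89,
              20.36, 21.76, 23.63, 25.30, 26.20, 26.36, 26.03, 25.03)
  data.frame(level = 1:17, label = levelLabels(),
             male_mean = male, female_mean = female,
             delta_mm = round(male - female, 2),
             delta_pct = round(100 * (male - female) / male, 1))
}

#' Published sex-specific wedge and biconcavity indices
#'
#' Reference cohort-mean anterior wedge index (Ha/Hp) and biconcavity index
#' (Hc/Hp) per level and sex, used to scale the generic mean height curve
#' into distinct anterior/central/posterior curves.
#'
#' @return data.frame with columns \code{level}, \code{label},
#'   \code{wedge_male}, \code{wedge_female}, \code{biconcavity_male},
#'   \code{biconcavity_female}.
#' @export
vertebraReferenceIndices <- function() {
  data.frame(
    level = 1:17, label = levelLabels(),
    wedge_male = c(0.93, 0.94, 0.96, 0.96, 0.97, 0.92, 0.92, 0.97, 0.94,
                   0.94, 0.88, 0.87, 0.89, 0.94, 1.00, 1.03, 1.20),
    wedge_female = c(0.94, 0.96, 0.99, 0.94, 0.98, 0.93, 0.92, 0.97, 0.96,
                     0.94, 0.91, 0.92, 0.93, 0.97, 1.04, 1.08, 1.19),
    biconcavity_male = c(0.86, 0.87, 0.87, 0.87, 0.86, 0.85, 0.86, 0.90,
                         0.89, 0.89, 0.86, 0.87, 0.87, 0.88, 0.89, 0.94, 1.01),
    biconcavity_female = c(0.86, 0.84, 0.88, 0.87, 0.85, 0.83, 0.85, 0.89,
                           0.87, 0.85, 0.85, 0.86, 0.88, 0.88, 0.91, 0.95, 1.01))
}

#' Default per-level, per-sex mean curves for Ha, Hp and Hc
#'
#' Treats the published mean height table as the posterior-height curve and
#' derives the anterior and central curves by multiplying with the
#' cohort-mean wedge and biconcavity indices, yielding an S-shaped mean
#' curve with a sex offset for each of the three height types.
#'
#' @return numeric array [17 x 2 x 3] with dimnames
#'   \code{levelLabels() x c("male","female") x c("Ha","Hp","Hc")}.
#' @export
defaultMeanCurve <- function() {
  hm <- vertebraReferenceMeans()
  ix <- vertebraReferenceIndices()
  arr <- array(NA_real_, dim = c(17, 2, 3),
               dimnames = list(levelLabels(), c("male", "female"),
                               c("Ha", "Hp", "Hc")))
  arr[, "male", "Hp"] <- hm$male_mean
  arr[, "female", "Hp"] <- hm$female_mean
  arr[, "male", "Ha"] <- hm$male_mean * ix$wedge_male
  arr[, "female", "Ha"] <- hm$female_mean * ix$wedge_female
  arr[, "male", "Hc"] <- hm$male_mean * ix$biconcavity_male
  arr[, "female", "Hc"] <- hm$female_mean * ix$biconcavity_female
  arr
}

#' Construct a cohort-generation specification
#'
#' Defaults describe the reference study conditions: 262 subjects with
#' 129 males, the published sex-specific mean curves, a 2 mm between-subject
#' random intercept SD, a 0.1 mm/level random slope SD and a 1.5 mm residual
#' SD.
#'
#' @param nSubjects number of subjects.
#' @param sexRatio fraction of males.
#' @param meanCurve 17 x 2 x 3 mean-height array (see
#'   \code{\link{defaultMeanCurve}}).
#' @param sdIntercept,sdSlope,sdResidual generative SDs in mm (slope per
#'   level step).
#' @param seed RNG seed.
#' @return a validated \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nSubjects = 262, sexRatio = 129 / 262,
                       meanCurve = defaultMeanCurve(),
                       sdIntercept = 2, sdSlope = 0.1, sdResidual = 1.5,
                       seed = 1) {
  new("CohortSpec", nSubjects = nSubjects, sexRatio = sexRatio,
      meanCurve = meanCurve, sdIntercept = sdIntercept, sdSlope = sdSlope,
      sdResidual = sdResidual, seed = seed)
}

#' Simulate a vertebral height cohort with known generative parameters
#'
#' Generates one record per subject and level with
#' \code{H = meanCurve[level, sex, type] + b0_i + b1_i * level + eps},
#' where \code{b0_i ~ N(0, sdIntercept^2)} and \code{b1_i ~ N(0, sdSlope^2)}
#' are drawn once per subject (shared by the three height types, as the
#' subject's overall size and cranio-caudal trend) and
#' \code{eps ~ N(0, sdResidual^2)} independently per record and type.
#' Reproducible: the same spec (including its seed) always yields the same
#' table.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return list with \code{records} (data.frame: \code{subject_id},
#'   \code{sex}, \code{level}, \code{Ha}, \code{Hp}, \code{Hc}) and
#'   \code{truth} (the generative parameters, including the per-subject
#'   random effects actually drawn).
#' @export
makeHeightCohort <- function(spec) {
  validObject(spec)
  n <- as.integer(spec@nSubjects)
  nMale <- round(spec@sexRatio * n)
  sex <- rep(c("male", "female"), c(nMale, n - nMale))
  withSeed(spec@seed, {
    b0 <- stats::rnorm(n, 0, spec@sdIntercept)
    b1 <- stats::rnorm(n, 0, spec@sdSlope)
    lv <- 1:17
    rec <- expand.grid(subject_id = seq_len(n), level = lv,
                       KEEP.OUT.ATTRS = FALSE)
    rec <- rec[order(rec$subject_id, rec$level), ]
    rec$sex <- sex[rec$subject_id]
    base <- b0[rec$subject_id] + b1[rec$subject_id] * rec$level
    sexIdx <- ifelse(rec$sex == "male", 1L, 2L)
    for (type in c("Ha", "Hp", "Hc")) {
      mu <- spec@meanCurve[cbind(rec$level, sexIdx,
                                 match(type, c("Ha", "Hp", "Hc")))]
      rec[[type]] <- mu + base +
        stats::rnorm(nrow(rec), 0, spec@sdResidual)
    }
    rownames(rec) <- NULL
    list(records = rec[, c("subject_id", "sex", "level", "Ha", "Hp", "Hc")],
         truth = list(meanCurve = spec@meanCurve, b0 = b0, b1 = b1,
                      sdIntercept = spec@sdIntercept, sdSlope = spec@sdSlope,
                      sdResidual = spec@sdResidual, sex = sex))
  })
}

#' Mean curve defined by a truncated-power spline coefficient vector
#'
#' Builds a 17 x 2 x 3 mean-curve array whose female curve is the spline
#' polynomial evaluated at levels 1..17 and whose male curve adds the sex
#' coefficient -- the generative twin of the regression model, useful for
#' parameter-recovery simulations.
#'
#' @param beta named coefficients \code{(Intercept)}, \code{ver},
#'   \code{ver2}, \code{ver3}, then one \code{tp<k>} per knot.
#' @param sexEffect additive male offset in mm (the beta11 analogue).
#' @param knots interior knots on the level axis.
#' @return numeric array [17 x 2 x 3]; identical for the three height types.
#' @export
splineMeanCurve <- function(beta, sexEffect, knots = c(9, 13)) {
  lv <- 1:17
  X <- cbind(1, lv, lv^2, lv^3)
  for (k in knots) X <- cbind(X, pmax(lv - k, 0)^3)
  mu <- drop(X %*% beta)
  arr <- array(NA_real_, dim = c(17, 2, 3),
               dimnames = list(levelLabels(), c("male", "female"),
                               c("Ha", "Hp", "Hc")))
  for (type in c("Ha", "Hp", "Hc")) {
    arr[, "male", type] <- mu + sexEffect
    arr[, "female", type] <- mu
  }
  arr
}
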