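# Truncated-power spline design and mixed-model machinery.

test_that("truncated-power terms switch on above the knots", {
  d <- buildSplineDesign(c(1, 13, 17), knots = c(9, 13))
  expect_equal(d$tp9, c(0, 64, 512))
  expect_equal(d$tp13, c(0, 0, 64))
  expect_equal(d$ver3, c(1, 13^3, 17^3))
  expect_error(buildSplineDesign(c(0, 5)), "levels")
  expect_error(buildSplineDesign(5, knots = 17), "knots")
  lin <- buildSplineDesign(c(5, 12), knots = c(9, 13), basis = "linear")
  expect_equal(lin$lin9, c(0, 3))
})

test_that("the cubic spline mean function is C2 at the knots", {
  beta <- referenceSplineBeta()
  f <- function(x) beta[1] + beta[2] * x + beta[3] * x^2 + beta[4] * x^3 +
    beta[5] * pmax(x - 9, 0)^3 + beta[6] * pmax(x - 13, 0)^3
  h <- 1e-5
  for (k in c(9, 13)) {
    for (deriv in 0:2) {
      num <- function(x) switch(deriv + 1,
        f(x),
        (f(x + h) - f(x - h)) / (2 * h),
        (f(x + h) - 2 * f(x) + f(x - h)) / h^2)
      expect_equal(num(k - 2 * h), num(k + 2 * h), tolerance = 1e-3,
                   label = sprintf("derivative %d at knot %d", deriv, k))
    }
  }
})

test_that("noise-free data reproduce the generating coefficients", {
  beta <- referenceSplineBeta()
  curve <- splineMeanCurve(beta, sexEffect = 1.4)
  coh <- makeHeightCohort(cohortSpec(nSubjects = 30, sexRatio = 0.5,
                                     meanCurve = curve, sdIntercept = 0,
                                     sdSlope = 0, sdResidual = 0,
                                     seed = 4))$records
  fit <- fitMixedSpline(coh, "Hp", randomEffects = "none")
  truth <- c(beta, male = 1.4)
  expect_equal(fit@coefficients[names(truth)], truth, tolerance = 1e-6)
})

test_that("with random effects off the fit equals direct least squares", {
  coh <- makeHeightCohort(cohortSpec(nSubjects = 40, seed = 6))$records
  fit <- fitMixedSpline(coh, "Hp", randomEffects = "none")
  X <- cbind(1, as.matrix(buildSplineDesign(coh$level, coh$sex)))
  betaLS <- qr.solve(X, coh$Hp)
  expect_equal(unname(fit@coefficients), unname(betaLS), tolerance = 1e-8)
})

test_that("single-level data raise a rank error", {
  coh <- data.frame(subject_id = rep(1:10, 2), sex = "male", level = 5,
                    Ha = rnorm(20, 20), Hp = rnorm(20, 20), Hc = rnorm(20, 18))
  expect_error(fitMixedSpline(coh, "Hp"), "rank error")
})

test_that("mixed fit recovers variance components and beats OLS", {
  beta <- referenceSplineBeta()
  curve <- splineMeanCurve(beta, sexEffect = 1.4)
  okSD <- 0; okAIC <- 0; okSex <- 0
  nrep <- 20
  for (r in seq_len(nrep)) {
    coh <- makeHeightCohort(cohortSpec(nSubjects = 262, meanCurve = curve,
                                       sdIntercept = 2, sdSlope = 0,
                                       sdResidual = 1,
                                       seed = 4000 + r))$records
    fit <- fitMixedSpline(coh, "Hp")
    okSD <- okSD + (fit@ranefSD["sdIntercept"] >= 1.8 &&
                      fit@ranefSD["sdIntercept"] <= 2.2)
    ols <- fitMixedSpline(coh, "Hp", randomEffects = "none")
    okAIC <- okAIC + (fit@AIC < ols@AIC)
    okSex <- okSex + (fit@coefficients["male"] > 0)
  }
  expect_gte(okSD / nrep, 0.9)
  expect_gte(okAIC / nrep, 0.95)
  expect_gte(okSex / nrep, 0.95)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  # linear mean with population variance ~4, random intercept 1, residual 1
  lv <- 1:17
  s <- sqrt(4 / (mean(lv^2) - mean(lv)^2))
  curve <- array(rep(20 + s * lv, 6), dim = c(17, 2, 3),
                 dimnames = list(levelLabels(), c("male", "female"),
                                 c("Ha", "Hp", "Hc")))
  coh <- makeHeightCohort(cohortSpec(nSubjects = 500, meanCurve = curve,
                                     sdIntercept = 1, sdSlope = 0,
                                     sdResidual = 1, seed = 31))$records
  fit <- fitMixedSpline(coh, "Hp", includeSex = FALSE)
  r2 <- r2Nakagawa(fit)
  expect_equal(unname(r2["R2marginal"]), 4 / 6, tolerance = 0.03)
  expect_equal(unname(r2["R2conditional"]), 5 / 6, tolerance = 0.03)
  # degenerate limits
  expect_equal(fit@R2marginal <= fit@R2conditional, TRUE)
})

test_that("linear spline recovers piecewise-linear truth", {
  lv <- 1:17
  mu <- 15 + 0.4 * lv + 1.1 * pmax(lv - 9, 0) - 1.3 * pmax(lv - 13, 0)
  curve <- array(rep(mu, 6), dim = c(17, 2, 3),
                 dimnames = list(levelLabels(), c("male", "female"),
                                 c("Ha", "Hp", "Hc")))
  coh <- makeHeightCohort(cohortSpec(nSubjects = 262, meanCurve = curve,
                                     sdIntercept = 1, sdSlope = 0,
                                     sdResidual = 1, seed = 41))$records
  fit <- fitLinearSpline(coh, "Hp", includeSex = FALSE)
  est <- fit@coefficients; se <- fit@seFixed
  truth <- c(15, 0.4, 1.1, -1.3)
  expect_true(all(abs(est[c("(Intercept)", "ver", "lin9", "lin13")] - truth)
                  <= 3 * se[c("(Intercept)", "ver", "lin9", "lin13")]))
  # strong cubic curvature: the cubic spline wins AIC over the linear spline
  beta <- referenceSplineBeta()
  coh2 <- makeHeightCohort(cohortSpec(nSubjects = 262,
                                      meanCurve = splineMeanCurve(beta, 1.4),
                                      sdIntercept = 2, sdSlope = 0,
                                      sdResidual = 1, seed = 42))$records
  expect_lt(fitMixedSpline(coh2, "Hp")@AIC, fitLinearSpline(coh2, "Hp")@AIC)
  # constant truth: all slopes ~ 0
  flat <- array(20, dim = c(17, 2, 3),
                dimnames = list(levelLabels(), c("male", "female"),
                                c("Ha", "Hp", "Hc")))
  coh3 <- makeHeightCohort(cohortSpec(nSubjects = 100, meanCurve = flat,
                                      sdIntercept = 0, sdSlope = 0,
                                      sdResidual = 0.5, seed = 43))$records
  fit3 <- fitLinearSpline(coh3, "Hp", includeSex = FALSE,
                          randomEffects = "none")
  expect_true(all(abs(fit3@coefficients[c("ver", "lin9", "lin13")]) < 0.05))
})

test_that("information criteria match their definitions and rank models", {
  coh <- makeHeightCohort(cohortSpec(nSubjects = 40, seed = 8))$records
  fit <- fitMixedSpline(coh, "Hp")
  ll <- logLik(fit@model)
  expect_equal(fit@AIC, -2 * as.numeric(ll) + 2 * attr(ll, "df"))
  expect_equal(fit@BIC, -2 * as.numeric(ll) + attr(ll, "df") * log(fit@nObs))
  expect_equal(fit@AIC, AIC(fit@model))
  cmp <- compareModels(list(a = fit, b = fit))
  expect_equal(cmp$AIC[1], cmp$AIC[2])
  other <- makeHeightCohort(cohortSpec(nSubjects = 41, seed = 8))$records
  fit2 <- fitMixedSpline(other, "Hp")
  expect_error(compareModels(list(fit, fit2)), "comparison error")
})

test_that("knot search returns single candidates trivially and prefers truth", {
  coh <- makeHeightCohort(cohortSpec(nSubjects = 40, seed = 12))$records
  ks <- knotSearch(coh, list(c(9, 13)), "Hp")
  expect_equal(ks$best, c(9, 13))
  expect_equal(nrow(ks$table), 1L)
  # pure cubic truth: the knot-free model wins
  lv <- 1:17
  beta0 <- qr.solve(cbind(1, lv, lv^2, lv^3),
                    defaultMeanCurve()[, "male", "Hp"])
  curve0 <- splineMeanCurve(c(beta0, 0, 0), sexEffect = 1.4)
  coh0 <- makeHeightCohort(cohortSpec(nSubjects = 262, meanCurve = curve0,
                                      sdIntercept = 2, sdSlope = 0,
                                      sdResidual = 1, seed = 51))$records
  ks0 <- knotSearch(coh0, list(numeric(0), c(9, 13)), "Hp")
  expect_equal(length(ks0$best), 0L)
})
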