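# Cohort statistics: delta tables, indices, tests, power, ICC, slopes.

test_that("sex delta table reproduces printed reference arithmetic", {
  coh <- referenceTwoSubjectCohort()
  tab <- sexDeltaTable(coh, "Hp")
  expect_equal(tab$delta_mm[tab$label == "T1"], 1.34)
  expect_equal(tab$delta_mm[tab$label == "T2"], 1.55)
  expect_equal(tab$delta_pct[tab$label == "T12"], 5.3)
  expect_equal(tab$delta_mm[tab$label == "L2"], 1.06)
  expect_equal(tab$delta_pct[tab$label == "L2"], 3.9)
  expect_equal(tab$delta_pct[tab$label == "L5"], 4.2)
})

test_that("delta_mm is antisymmetric under sex swap and zero for equal means", {
  coh <- referenceTwoSubjectCohort()
  swapped <- coh
  swapped$sex <- ifelse(coh$sex == "male", "female", "male")
  a <- sexDeltaTable(coh, "Hp")
  b <- sexDeltaTable(swapped, "Hp")
  expect_equal(b$delta_mm, -a$delta_mm)
  eq <- coh; eq$Hp <- 20
  tab <- sexDeltaTable(eq, "Hp")
  expect_true(all(tab$delta_mm == 0) && all(tab$delta_pct == 0))
})

test_that("wedge and biconcavity indices are ratios invariant to scaling", {
  coh <- data.frame(subject_id = 1, sex = "male", level = 1:2,
                    Ha = c(10, 12), Hp = c(10, 10), Hc = c(10, 9))
  wb <- wedgeBiconcavity(coh)
  expect_equal(wb$records$wedge, c(1.0, 1.2))
  expect_equal(wb$records$biconcavity, c(1.0, 0.9))
  sc <- coh; sc[, c("Ha", "Hp", "Hc")] <- sc[, c("Ha", "Hp", "Hc")] * 3.7
  expect_equal(wedgeBiconcavity(sc)$records[, c("wedge", "biconcavity")],
               wb$records[, c("wedge", "biconcavity")])
  bad <- coh; bad$Hp[1] <- 0
  expect_error(wedgeBiconcavity(bad), "invalid-record")
})

test_that("index means recover constant generating profiles", {
  mc <- defaultMeanCurve()
  coh <- makeHeightCohort(cohortSpec(nSubjects = 400, sdIntercept = 0,
                                     sdSlope = 0, sdResidual = 0.3,
                                     seed = 21))$records
  wb <- wedgeBiconcavity(coh)
  ix <- vertebraReferenceIndices()
  m <- wb$means[wb$means$sex == "male", ]
  # 2 SE of a ratio of two noisy heights at n ~ 200 males is well under 0.01
  expect_true(all(abs(m$wedge - ix$wedge_male) < 0.012))
  expect_true(all(abs(m$biconcavity - ix$biconcavity_male) < 0.012))
})

test_that("pooled t-test behaves correctly at its edges", {
  coh <- data.frame(subject_id = 1:8, sex = rep(c("male", "female"), 4),
                    level = 1, Ha = 1, Hp = rep(c(5, 5, 6, 6), 2), Hc = 1)
  tt <- perLevelTest(coh, "Hp")
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  set.seed(2)
  big <- data.frame(subject_id = 1:200,
                    sex = rep(c("male", "female"), each = 100), level = 1,
                    Ha = 1, Hp = c(rnorm(100, 5), rnorm(100, 0)), Hc = 1)
  expect_lt(perLevelTest(big, "Hp")$p, 1e-3)
  small <- coh[1:3, ]
  expect_identical(perLevelTest(small, "Hp")$flag, "insufficient")
})

test_that("pooled t-test agrees with a permutation test", {
  set.seed(8)
  x <- rnorm(20, 0.8); y <- rnorm(20)
  coh <- data.frame(subject_id = 1:40,
                    sex = rep(c("male", "female"), each = 20),
                    level = 1, Ha = 1, Hp = c(x, y), Hc = 1)
  p0 <- perLevelTest(coh, "Hp")$p
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  perm <- replicate(1e4, {
    s <- sample(40, 20)
    abs(mean(pool[s]) - mean(pool[-s]))
  })
  pPerm <- mean(perm >= obs)
  expect_lt(abs(p0 - pPerm), 0.02)
})

test_that("power formula matches its definition and limits", {
  expect_equal(powerTwoSample(50, 50, 0, 0.05), 0.05, tolerance = 1e-12)
  pw <- vapply(c(20, 50, 100, 400), function(n)
    powerTwoSample(n, n, 0.5), 0)
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[4], 0.999)
  expect_error(powerTwoSample(129, 133, 0.4, alpha = 1.2), "alpha")
})

test_that("power matches a Monte-Carlo estimate at the study group sizes", {
  p <- powerTwoSample(129, 133, 0.4, 0.05)
  set.seed(9)
  nrep <- 1e5
  x <- matrix(rnorm(129 * nrep), 129)
  y <- matrix(rnorm(133 * nrep, 0.4), 133)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- colSums((x - rep(mx, each = 129))^2)
  vy <- colSums((y - rep(my, each = 133))^2)
  tstat <- (my - mx) / sqrt((vx + vy) / 260 * (1 / 129 + 1 / 133))
  expect_lt(abs(p - mean(abs(tstat) > qt(0.975, 260))), 0.005)
})

test_that("icc2k matches the two-way ANOVA mean-squares oracle", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(5:40, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n)  # subject effect + noise
    d <- data.frame(y = as.vector(m), s = factor(rep(seq_len(n), k)),
                    rt = factor(rep(seq_len(k), each = n)))
    a <- anova(aov(y ~ s + rt, d))
    oracle <- (a["s", "Mean Sq"] - a["Residuals", "Mean Sq"]) /
      (a["s", "Mean Sq"] +
         (a["rt", "Mean Sq"] - a["Residuals", "Mean Sq"]) / n)
    expect_equal(icc2k(m), oracle, tolerance = 1e-10)
  }
})

test_that("icc2k hits its boundary cases", {
  set.seed(12)
  x <- rnorm(30, sd = 3)
  expect_equal(icc2k(cbind(x, x, x)), 1)
  expect_error(icc2k(matrix(5, 10, 2)), "undefined-ICC")
  # reader-study conditions: subject SD 3, rater noise SD 1, k = 2, n = 336
  m <- rnorm(336, sd = 3) + matrix(rnorm(672), 336, 2)
  expect_gt(icc2k(m), 0.9)
  expect_error(icc2k(matrix(1:6, 3, 2)), "subjects")
})

test_that("expected ICC decreases with rater noise", {
  set.seed(13)
  mean_icc <- vapply(c(0.5, 1.5, 3), function(sdNoise)
    mean(replicate(30, {
      m <- rnorm(60, sd = 3) + matrix(rnorm(120, sd = sdNoise), 60, 2)
      icc2k(m)
    })), 0)
  expect_true(all(diff(mean_icc) < 0))
})

test_that("segment slopes follow the first-difference definition", {
  expect_equal(unname(segmentMeanSlope(rep(7, 17), 5:8)), c(0, 0))
  curve <- 20 + 0:16
  s <- segmentMeanSlope(curve, 1:17)
  expect_equal(unname(s["slope_mm"]), 1)
  expect_equal(unname(s["slope_pct"]), mean(100 / (20:35)))
  # independent hand arithmetic on the reference male curve, T9..L1
  male <- vertebraReferenceMeans()$male_mean
  hand_mm <- ((22.13 - 20.47) + (23.24 - 22.13) + (24.94 - 23.24) +
                (26.84 - 24.94)) / 4
  hand_pct <- 100 * (1.66 / 20.47 + 1.11 / 22.13 + 1.70 / 23.24 +
                       1.90 / 24.94) / 4
  s2 <- segmentMeanSlope(male, 9:13)
  expect_equal(unname(s2["slope_mm"]), hand_mm, tolerance = 1e-12)
  expect_equal(unname(s2["slope_pct"]), hand_pct, tolerance = 1e-12)
  expect_error(segmentMeanSlope(male, 16:19), "out of range")
})

test_that("exclusion tally reconciles study bookkeeping", {
  t1 <- exclusionTally(3117, c(missegmented = 77, partial = 115))
  expect_equal(unname(t1["analyzed"]), 2925)
  expect_equal(unname(t1["excluded_pct"]), 6.16)
  expect_equal(unname(t1["measurements"]), 8775)
  expect_error(exclusionTally(10, 11), "excluded")
})
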