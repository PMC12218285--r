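# Mask-to-heights landmark algorithm.

test_that("binarize maps any labels to 0/255 and is idempotent", {
  g <- matrix(0L, 5, 5); g[2:4, 2:4] <- 7L
  b <- binarize(g)
  expect_true(all(maskMatrix(b) %in% c(0L, 255L)))
  expect_identical(sum(maskMatrix(b) == 255L), 9L)
  expect_identical(maskMatrix(binarize(b)), maskMatrix(b))
  expect_identical(maskMatrix(binarize(matrix(0L, 3, 3))), matrix(0L, 3, 3))
})

test_that("rectangle corners are recovered exactly", {
  res <- makeVertebraMask(vertebraShape(20, 20, 30))
  v <- approximateQuadrilateral(res$mask)
  # the 4 extreme corner pixels of the rasterized rectangle
  m <- maskMatrix(res$mask) > 0
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  want <- rbind(c(rows[1], cols[1]), c(rows[1], cols[2]),
                c(rows[2], cols[2]), c(rows[2], cols[1]))
  expect_equal(v[order(v[, 1], v[, 2]), ],
               want[order(want[, 1], want[, 2]), ], tolerance = 1e-9)
})

test_that("corners of rotated and biconcave bodies stay near truth", {
  res <- makeVertebraMask(vertebraShape(20, 20, 30, rotation = 30))
  v <- approximateQuadrilateral(res$mask)
  tc <- trueCorners(res$truth) + 1   # mm -> pixel units at spacing 1
  for (k in 1:4) {
    d <- sqrt(apply(sweep(tc, 2, v[k, ])^2, 1, sum))
    expect_lt(min(d), 1.5)
  }
  res2 <- makeVertebraMask(vertebraShape(22, 21, 30, concavitySuperior = 2.5,
                                         concavityInferior = 2))
  v2 <- approximateQuadrilateral(res2$mask)
  tc2 <- trueCorners(res2$truth) + 1
  for (k in 1:4) {
    d <- sqrt(apply(sweep(tc2, 2, v2[k, ])^2, 1, sum))
    expect_lt(min(d), 2)
  }
})

test_that("polygon approximation fails cleanly on degenerate shapes", {
  line <- matrix(0L, 10, 40); line[5, 3:38] <- 255L
  mask <- new("VertebraMask2D", mask = line, spacing = c(1, 1),
              anteriorLow = TRUE)
  expect_error(approximateQuadrilateral(mask), "approximation-failure|fewer")
  tiny <- matrix(0L, 6, 6); tiny[3:4, 3:4] <- 255L
  expect_error(approximateQuadrilateral(
    new("VertebraMask2D", mask = tiny, spacing = c(1, 1), anteriorLow = TRUE)),
    "16 pixels")
})

test_that("corner labeling follows the orientation convention", {
  v <- rbind(c(1, 1), c(1, 30), c(20, 1), c(20, 30))
  lm <- labelCorners(v)
  expect_equal(lm@AS, c(1, 1)); expect_equal(lm@PS, c(1, 30))
  expect_equal(lm@AI, c(20, 1)); expect_equal(lm@PI, c(20, 30))
  lmF <- labelCorners(v, anteriorLow = FALSE)
  expect_equal(lmF@AS, c(1, 30)); expect_equal(lmF@AI, c(20, 30))
  expect_error(labelCorners(rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 3))),
               "degenerate")
  expect_error(labelCorners(rbind(c(1, 1), c(1, 5), c(1, 9), c(5, 5))),
               "collinear")
})

test_that("central landmarks follow the Bresenham midpoint search", {
  # solid rectangle: midpoints already on the mask
  res <- makeVertebraMask(vertebraShape(20, 20, 30))
  ex <- extractHeights(res$mask)
  lm <- ex$landmarks
  expect_equal(lm@CS, vertmorph:::roundHalfUp((lm@AS + lm@PS) / 2))
  expect_equal(lm@CI, vertmorph:::roundHalfUp((lm@AI + lm@PI) / 2))
  # biconcave body: CS moves ~2 px caudal of the superior midpoint
  res2 <- makeVertebraMask(vertebraShape(20, 20, 30, concavitySuperior = 2,
                                         concavityInferior = 2))
  lm2 <- extractHeights(res2$mask)$landmarks
  mSup <- vertmorph:::roundHalfUp((lm2@AS + lm2@PS) / 2)
  mInf <- vertmorph:::roundHalfUp((lm2@AI + lm2@PI) / 2)
  expect_equal(lm2@CS[1] - mSup[1], 2, tolerance = 1.0001)
  expect_equal(mInf[1] - lm2@CI[1], 2, tolerance = 1.0001)
  # ring hollowed along the whole midline: failure
  m <- maskMatrix(res$mask)
  mid <- round(mean(range(which(colSums(m > 0) > 0))))
  m[, (mid - 2):(mid + 2)] <- 0L
  # restore top/bottom strips so corners remain but midline is empty
  ring <- new("VertebraMask2D", mask = m, spacing = c(1, 1),
              anteriorLow = TRUE)
  crn <- labelCorners(rbind(c(4, 4), c(4, 34), c(24, 4), c(24, 34)))
  expect_error(centralLandmarks(ring, crn), "central-landmark-failure")
})

test_that("heights are Euclidean distances with per-axis mm scaling", {
  lm <- new("LandmarkSet", AS = c(0, 0), PS = c(0, 20), AI = c(12, 0),
            PI = c(10, 20), CS = c(0, 10), CI = c(10, 10))
  h <- computeHeights(lm, c(1, 1))
  expect_equal(unname(h), c(12, 10, 10))
  h2 <- computeHeights(lm, c(0.7, 1))
  expect_equal(unname(h2[3]), 7)
  res <- makeVertebraMask(vertebraShape(16, 16, 24, spacing = c(0.8, 0.8)))
  expect_equal(unname(extractHeights(res$mask)$heights), rep(16, 3),
               tolerance = 1e-9)
  lm0 <- new("LandmarkSet", AS = c(0, 0), PS = c(0, 20), AI = c(12, 0),
             PI = c(10, 20), CS = c(5, 10), CI = c(5, 10))
  expect_error(computeHeights(lm0, c(1, 1)), "degenerate-landmark")
})

test_that("bresenhamLine is an 8-connected digital segment", {
  p <- bresenhamLine(c(1, 1), c(4, 9))
  expect_equal(p[1, ], c(row = 1, col = 1))
  expect_equal(p[nrow(p), ], c(row = 4, col = 9))
  steps <- abs(diff(p))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))
  expect_equal(nrow(bresenhamLine(c(3, 3), c(3, 3))), 1L)
})

test_that("midsagittal slice is picked at the two-largest-objects centroid", {
  sv <- makeSpineVolume(3, vertebraShape(20, 19, 30))
  sl <- extractMidsagittalSlice(sv, 2)
  expect_true(all(maskMatrix(sl) %in% c(0L, 255L)))
  expect_error(extractMidsagittalSlice(sv, 9), "missing-label")
  # asymmetric two-component toy volume: oracle = rounded mean sagittal
  # coordinate of the union of the two largest components
  vol <- array(0L, dim = c(20, 20, 20))
  vol[5:14, 5:14, 8:12] <- 1L            # body, 500 voxels around slice 10
  vol[8:11, 16:18, 13:15] <- 1L          # process, 36 voxels around 14
  pos <- which(vol == 1L, arr.ind = TRUE)
  oracle <- floor(mean(pos[, 3]) + 0.5)
  v3 <- new("VertebraMask3D", volume = vol, spacing = c(1, 1, 1),
            sagittalAxis = 3L, anteriorLow = TRUE)
  sl2 <- extractMidsagittalSlice(v3, 1)
  expect_identical(sum(maskMatrix(sl2) > 0),
                   sum(vol[, , oracle] == 1L))
})

test_that("posterior-element removal keeps the anterior body", {
  # body-only mask: unchanged
  res <- makeVertebraMask(vertebraShape(20, 20, 30))
  out <- removePosteriorElements(binarize(res$mask))
  expect_identical(maskMatrix(out), maskMatrix(binarize(res$mask)))
  # body + process joined by a thin bridge (from the volume generator)
  sv <- makeSpineVolume(1, vertebraShape(20, 19, 30))
  sl <- extractMidsagittalSlice(sv, 1)
  body <- removePosteriorElements(sl)
  truthArea <- sum(maskMatrix(makeVertebraMask(vertebraShape(20, 19, 30))$mask) > 0)
  expect_lt(abs(sum(maskMatrix(body) > 0) - truthArea) / truthArea, 0.05)
  # two disjoint components: keep the more anterior large one, no opening
  m <- matrix(0L, 30, 60)
  m[5:25, 5:30] <- 255L          # anterior body
  m[10:20, 40:55] <- 255L        # posterior blob (>= 25% area)
  disj <- new("VertebraMask2D", mask = m, spacing = c(1, 1),
              anteriorLow = TRUE)
  kept <- maskMatrix(removePosteriorElements(disj))
  expect_identical(sum(kept > 0), 21L * 26L)
  expect_true(all(which(colSums(kept > 0) > 0) <= 30))
  expect_error(removePosteriorElements(
    new("VertebraMask2D", mask = matrix(0L, 4, 4), spacing = c(1, 1),
        anteriorLow = TRUE)), "empty-input")
})

test_that("extraction is rotation-robust and orientation-equivariant", {
  base <- trueHeights(makeVertebraMask(vertebraShape(21, 19, 30))$truth)
  for (rot in c(-20, -10, 10, 20)) {
    res <- makeVertebraMask(vertebraShape(21, 19, 30, rotation = rot))
    h <- chainHeights(res)
    expect_true(all(abs(h - base) <= 2), label = paste("rotation", rot))
  }
  set.seed(5)
  for (i in 1:10) {
    sp <- runif(2, 0.6, 1.4)
    res <- makeVertebraMask(vertebraShape(runif(1, 15, 25), runif(1, 15, 25),
                                          30,
                                          concavitySuperior = runif(1, 0, 2),
                                          concavityInferior = runif(1, 0, 2),
                                          rotation = runif(1, -15, 15),
                                          spacing = sp))
    h1 <- chainHeights(res)
    mm <- maskMatrix(res$mask)
    flipped <- list(mask = new("VertebraMask2D", mask = mm[, ncol(mm):1],
                               spacing = sp, anteriorLow = FALSE))
    h2 <- extractHeights(removePosteriorElements(flipped$mask))$heights
    expect_equal(h1, h2, tolerance = 1e-9)
  }
})

test_that("volume-to-heights round trip recovers per-level truth", {
  spec <- vertebraShape(20, 19, 30, concavitySuperior = 1.5,
                        concavityInferior = 1.5)
  truth <- trueHeights(makeVertebraMask(spec)$truth)
  sv <- makeSpineVolume(3, spec)
  for (l in 1:3) {
    body <- removePosteriorElements(extractMidsagittalSlice(sv, l))
    h <- extractHeights(body)$heights
    expect_true(all(abs(h - truth) <= 2 * max(pixelSpacing(body))),
                label = paste("level", l))
  }
})
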