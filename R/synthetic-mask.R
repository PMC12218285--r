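#' Construct a synthetic vertebral body specification
#'
#' Builds a \linkS4class{MaskSpec} describing one vertebral body in
#' continuous mm coordinates (rows caudal, columns posterior). The body is a
#' simple quadrilateral with optional circular-segment endplate concavities,
#' an in-plane rotation and normal boundary jitter.
#'
#' @param cornerAS,cornerPS,cornerAI,cornerPI numeric(2) corner positions in
#'   mm (anterior/posterior x superior/inferior).
#' @param concavitySuperior,concavityInferior central concavity depths in mm.
#' @param rotation in-plane rotation in degrees about the shape centroid.
#' @param spacing numeric(2) (row, col) pixel spacing in mm.
#' @param boundaryNoiseSD SD in mm of iid normal jitter applied to the
#'   contour before rasterization.
#' @return a validated \linkS4class{MaskSpec}.
#' @seealso \code{\link{vertebraShape}} for a height/width parameterization.
#' @export
maskSpec <- function(cornerAS, cornerPS, cornerAI, cornerPI,
                     concavitySuperior = 0, concavityInferior = 0,
                     rotation = 0, spacing = c(1, 1), boundaryNoiseSD = 0) {
  new("MaskSpec",
      cornerAS = as.numeric(cornerAS), cornerPS = as.numeric(cornerPS),
      cornerAI = as.numeric(cornerAI), cornerPI = as.numeric(cornerPI),
      concavitySuperior = concavitySuperior,
      concavityInferior = concavityInferior,
      rotation = rotation, spacing = as.numeric(spacing),
      boundaryNoiseSD = boundaryNoiseSD)
}

#' Vertebra-like trapezoid specification from heights and width
#'
#' Convenience wrapper around \code{\link{maskSpec}}: anterior edge of length
#' \code{heightA} at column 0, posterior edge of length \code{heightP} at
#' column \code{width}, vertically centered, so the true anterior/posterior
#' heights equal the arguments exactly.
#'
#' @param heightA,heightP anterior and posterior edge lengths in mm.
#' @param width antero-posterior body width in mm.
#' @param ... passed on to \code{\link{maskSpec}}.
#' @return a \linkS4class{MaskSpec}.
#' @export
#' @examples
#' sp <- vertebraShape(20, 20, 30)
#' res <- makeVertebraMask(sp, seed = 1)
#' trueHeights(res$truth)
vertebraShape <- function(heightA, heightP, width, ...) {
  off <- (heightA - heightP) / 2
  maskSpec(cornerAS = c(0, 0), cornerPS = c(off, width),
           cornerAI = c(heightA, 0), cornerPI = c(off + heightP, width), ...)
}

# Circle describing a circular-segment endplate bite of central depth d,
# entered from edge midpoint m along unit direction u (toward the interior).
# Chord width is half the edge length.
.concavityCircle <- function(m, u, d, edgeLen) {
  if (d <= 0) return(NULL)
  a <- edgeLen / 4                       # half-chord
  R <- (a^2 + d^2) / (2 * d)
  list(center = m - (R - d) * u, R = R, depth = d)
}

# Ray-casting point-in-polygon with inclusive boundary (tolerance in mm).
.pointsInPoly <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  onb <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    onb <- onb | (.segDist(pts, poly[i, ], poly[j, ]) <= tol)
  }
  inside | onb
}

#' Generate a synthetic vertebral body mask with exact ground truth
#'
#' Rasterizes the continuous shape described by a \linkS4class{MaskSpec}
#' onto a pixel grid: a pixel is foreground iff its center lies inside the
#' (rotated, optionally jittered) quadrilateral and outside both endplate
#' concavity bites; boundary pixels count as inside. The shape is anchored
#' so that its bounding-box corner falls on a pixel center, with a 3-pixel
#' background margin. The returned truth holds the exact continuous-space
#' corner and central endplate positions (in mm, raster frame) and the true
#' heights: \code{Ha = |AS - AI|}, \code{Hp = |PS - PI|}, and
#' \code{Hc} = distance between the endplate midpoints minus the two
#' concavity depths.
#'
#' @param spec a \linkS4class{MaskSpec}.
#' @param seed integer seed driving the boundary jitter (ignored when
#'   \code{boundaryNoiseSD = 0}); the same (spec, seed) pair always yields
#'   the identical mask.
#' @param gridSize optional (nrow, ncol); when given, the shape must fit
#'   with a 2-pixel margin or a size error is raised.
#' @return list with elements \code{mask} (\linkS4class{VertebraMask2D}) and
#'   \code{truth} (\linkS4class{LandmarkTruth}).
#' @export
makeVertebraMask <- function(spec, seed = NULL, gridSize = NULL) {
  validObject(spec)
  sr <- spec@spacing[1]; sc <- spec@spacing[2]

  corners <- rbind(AS = spec@cornerAS, PS = spec@cornerPS,
                   AI = spec@cornerAI, PI = spec@cornerPI)
  mSup <- (corners["AS", ] + corners["PS", ]) / 2
  mInf <- (corners["AI", ] + corners["PI", ]) / 2
  u <- mInf - mSup
  u <- u / sqrt(sum(u^2))
  circSup <- .concavityCircle(mSup, u, spec@concavitySuperior,
                              .euclid(corners["AS", ], corners["PS", ]))
  circInf <- .concavityCircle(mInf, -u, spec@concavityInferior,
                              .euclid(corners["AI", ], corners["PI", ]))

  # rotate everything about the quad centroid
  th <- spec@rotation * pi / 180
  ctr <- colMeans(corners)
  rot <- function(p) {
    dp <- p - ctr
    ctr + c(cos(th) * dp[1] - sin(th) * dp[2],
            sin(th) * dp[1] + cos(th) * dp[2])
  }
  corners <- t(apply(corners, 1, rot))
  mSup <- rot(mSup); mInf <- rot(mInf)
  if (!is.null(circSup)) circSup$center <- rot(circSup$center)
  if (!is.null(circInf)) circInf$center <- rot(circInf$center)
  uR <- (mInf - mSup); uR <- uR / sqrt(sum(uR^2))

  # translate so the bounding-box minimum sits on the center of pixel
  # (margin+1, margin+1); pixel (i, j) center is at ((i-1)*sr, (j-1)*sc)
  margin <- 3L
  bbMin <- apply(corners, 2, min)
  shift <- c(margin * sr - bbMin[1], margin * sc - bbMin[2])
  tr <- function(p) p + shift
  corners <- sweep(corners, 2, shift, "+")
  mSup <- tr(mSup); mInf <- tr(mInf)
  if (!is.null(circSup)) circSup$center <- tr(circSup$center)
  if (!is.null(circInf)) circInf$center <- tr(circInf$center)

  bbMax <- apply(corners, 2, max)
  nr <- ceiling(bbMax[1] / sr) + 1L + margin
  nc <- ceiling(bbMax[2] / sc) + 1L + margin
  if (!is.null(gridSize)) {
    if (gridSize[1] < nr - 1L || gridSize[2] < nc - 1L)
      stop("size error: shape (plus a 2-pixel margin) exceeds the requested grid")
    nr <- gridSize[1]; nc <- gridSize[2]
  }

  centers <- cbind(rep((seq_len(nr) - 1) * sr, times = nc),
                   rep((seq_len(nc) - 1) * sc, each = nr))

  polyOrder <- corners[c("AS", "PS", "PI", "AI"), , drop = FALSE]
  if (spec@boundaryNoiseSD > 0) {
    contour <- .denseContour(polyOrder, circSup, circInf, uR,
                             step = min(sr, sc) / 4)
    contour <- withSeed(seed, contour +
                          matrix(stats::rnorm(length(contour), 0,
                                              spec@boundaryNoiseSD),
                                 ncol = 2))
    fg <- pracma::inpolygon(centers[, 1], centers[, 2],
                            contour[, 1], contour[, 2])
  } else {
    fg <- .pointsInPoly(centers, polyOrder)
    for (circ in list(circSup, circInf)) {
      if (is.null(circ)) next
      d2 <- (centers[, 1] - circ$center[1])^2 + (centers[, 2] - circ$center[2])^2
      fg <- fg & !(d2 < (circ$R - 1e-9)^2)
    }
  }

  mat <- matrix(0L, nr, nc)
  mat[matrix(fg, nr, nc)] <- 255L

  truth <- new("LandmarkTruth",
               corners = corners,
               centralSuperior = mSup + spec@concavitySuperior * uR,
               centralInferior = mInf - spec@concavityInferior * uR,
               Ha = .euclid(corners["AS", ], corners["AI", ]),
               Hp = .euclid(corners["PS", ], corners["PI", ]),
               Hc = .euclid(mSup, mInf) -
                 spec@concavitySuperior - spec@concavityInferior)

  list(mask = new("VertebraMask2D", mask = mat,
                  spacing = spec@spacing, anteriorLow = TRUE),
       truth = truth)
}

# Densely sampled closed contour of the quad with concavity arcs substituted
# into the superior (AS-PS) and inferior (PI-AI) edges.
.denseContour <- function(poly, circSup, circInf, u, step) {
  sampleSeg <- function(a, b) {
    n <- max(2L, ceiling(.euclid(a, b) / step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  # arc of `circ` replacing the middle of edge a->b; uIn is the interior
  # direction at the edge midpoint
  edgeWithBite <- function(a, b, circ, uIn) {
    if (is.null(circ)) return(sampleSeg(a, b))
    m <- (a + b) / 2
    eDir <- (b - a); eDir <- eDir / sqrt(sum(eDir^2))
    # chord endpoints: solve |m + t*eDir - center| = R for t
    toM <- m - circ$center
    proj <- sum(toM * eDir)
    disc <- proj^2 - sum(toM^2) + circ$R^2
    half <- sqrt(max(0, disc))
    c1 <- m + (-proj - half) * eDir
    c2 <- m + (-proj + half) * eDir      # c1 -> c2 runs along a -> b
    # sweep the arc from c1 to c2 passing through the deepest bite point
    ang <- function(p) atan2(p[2] - circ$center[2], p[1] - circ$center[1])
    a1 <- ang(c1); a2 <- ang(c2); ad <- ang(m + circ$depth * uIn)
    ccw <- (a2 - a1) %% (2 * pi)
    adr <- (ad - a1) %% (2 * pi)
    angles <- if (adr <= ccw) seq(a1, a1 + ccw, length.out = 32L)
              else seq(a1, a1 - (2 * pi - ccw), length.out = 32L)
    arc <- cbind(circ$center[1] + circ$R * cos(angles),
                 circ$center[2] + circ$R * sin(angles))
    rbind(sampleSeg(a, c1), arc[-nrow(arc), , drop = FALSE],
          sampleSeg(c2, b))
  }
  # poly rows: AS, PS, PI, AI
  rbind(edgeWithBite(poly[1, ], poly[2, ], circSup, u),     # superior edge
        sampleSeg(poly[2, ], poly[3, ]),                    # posterior edge
        edgeWithBite(poly[3, ], poly[4, ], circInf, -u),    # inferior edge
        sampleSeg(poly[4, ], poly[1, ]))                    # anterior edge
}
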