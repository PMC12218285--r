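# Mask-to-heights landmark algorithm: midsagittal slice selection, posterior
# element removal, 4-vertex contour approximation, Bresenham-corrected
# central landmarks, Euclidean heights.

# 3D connected components (6-connectivity) of a logical array; returns an
# integer vector of component ids parallel to `which(fg)`.
.components3D <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  if (!length(idx)) return(list(idx = integer(), comp = integer()))
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1) + (pos[, 2] - 1) * d[1] + (pos[, 3] - 1) * d[1] * d[2]
  lookup <- match(key, key)  # identity; used via match on neighbor keys
  edges <- NULL
  shifts <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (s in shifts) {
    np <- sweep(pos, 2, s, "+")
    ok <- np[, 1] <= d[1] & np[, 2] <= d[2] & np[, 3] <= d[3]
    nkey <- (np[, 1] - 1) + (np[, 2] - 1) * d[1] + (np[, 3] - 1) * d[1] * d[2]
    hit <- match(nkey[ok], key)
    from <- which(ok)[!is.na(hit)]
    to <- hit[!is.na(hit)]
    if (length(from)) edges <- rbind(edges, cbind(from, to))
  }
  n <- length(idx)
  if (is.null(edges)) {
    comp <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  list(idx = idx, pos = pos, comp = comp)
}

#' Extract the midsagittal slice of one vertebral level
#'
#' Finds the connected components of the requested label in the 3D volume,
#' takes the union of the (up to) two largest -- the vertebral body and the
#' posterior process -- and returns the sagittal 2D slice at the rounded
#' sagittal coordinate of that union's centroid, restricted to the label and
#' binarized.
#'
#' @param volume a \linkS4class{VertebraMask3D}.
#' @param label integer label of the level.
#' @return a \linkS4class{VertebraMask2D} (rows cranio-caudal, columns
#'   antero-posterior).
#' @export
extractMidsagittalSlice <- function(volume, label) {
  stopifnot(is(volume, "VertebraMask3D"))
  fg <- volume@volume == label
  if (!any(fg)) stop("missing-label error: label ", label, " not present")
  cc <- .components3D(fg)
  sizes <- tabulate(cc$comp)
  top <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
  sel <- cc$comp %in% top
  sag <- volume@sagittalAxis
  sliceIdx <- as.integer(roundHalfUp(mean(cc$pos[sel, sag])))

  perm <- c(setdiff(1:3, sag), sag)
  sliceMat <- switch(sag,
                     volume@volume[sliceIdx, , ],
                     volume@volume[, sliceIdx, ],
                     volume@volume[, , sliceIdx])
  m <- matrix(0L, nrow(sliceMat), ncol(sliceMat))
  m[sliceMat == label] <- 255L
  if (!any(m > 0))
    stop("degenerate-slice error: label ", label,
         " has no foreground in its centroid slice")
  new("VertebraMask2D", mask = m,
      spacing = volume@spacing[setdiff(1:3, sag)],
      anteriorLow = volume@anteriorLow)
}

#' Binarize a mask slice
#'
#' Sets every nonzero pixel to 255 and every zero pixel to 0 (idempotent on
#' already-binary input).
#'
#' @param x an integer/numeric matrix or a \linkS4class{VertebraMask2D}.
#' @param spacing,anteriorLow metadata used when \code{x} is a bare matrix.
#' @return a \linkS4class{VertebraMask2D}.
#' @export
binarize <- function(x, spacing = c(1, 1), anteriorLow = TRUE) {
  if (is(x, "VertebraMask2D")) {
    m <- x@mask; spacing <- x@spacing; anteriorLow <- x@anteriorLow
  } else m <- x
  out <- matrix(0L, nrow(m), ncol(m))
  out[m != 0] <- 255L
  new("VertebraMask2D", mask = out, spacing = as.numeric(spacing),
      anteriorLow = anteriorLow)
}

#' Remove posterior elements from a midsagittal vertebra slice
#'
#' Isolates the vertebral body: if the foreground is a single component, a
#' morphological opening with increasing disc radius is applied until the
#' foreground splits (or a radius cap is reached); among the resulting
#' components with at least \code{areaFloor} of the foreground area, the one
#' with the most anterior centroid is kept and its boundary is restored by a
#' conditional dilation with the same structuring element, constrained to
#' the original mask. Already-disjoint input skips the opening.
#'
#' @param slice a \linkS4class{VertebraMask2D}.
#' @param radiusCap maximum opening radius in pixels.
#' @param areaFloor minimum component area as a fraction of foreground area.
#' @return a \linkS4class{VertebraMask2D} containing only the body.
#' @export
removePosteriorElements <- function(slice, radiusCap = 10L, areaFloor = 0.25) {
  stopifnot(is(slice, "VertebraMask2D"))
  fg <- slice@mask > 0
  if (!any(fg)) stop("empty-input error: mask has no foreground")
  anterior <- slice@anteriorLow

  pickAnterior <- function(lab) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= areaFloor * sum(sizes))
    if (!length(keep)) keep <- which.max(sizes)
    cols <- vapply(keep, function(k) {
      mean(which(lab == k, arr.ind = TRUE)[, 2])
    }, 0)
    keep[if (anterior) which.min(cols) else which.max(cols)]
  }

  lab0 <- EBImage::bwlabel(fg)
  if (max(lab0) >= 2L) {
    body <- lab0 == pickAnterior(lab0)
    out <- matrix(0L, nrow(fg), ncol(fg)); out[body] <- 255L
    return(new("VertebraMask2D", mask = out, spacing = slice@spacing,
               anteriorLow = anterior))
  }

  storage.mode(fg) <- "integer"
  for (r in seq_len(radiusCap)) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    opened <- EBImage::opening(fg, brush)
    lab <- EBImage::bwlabel(opened > 0)
    if (max(lab) >= 2L) {
      sizes <- tabulate(lab[lab > 0])
      # a true body/process split detaches a component below the area
      # floor; two comparably-sized pieces mean the opening cut through
      # the body itself (e.g. a deep biconcave waist): nothing to remove
      if (all(sizes >= areaFloor * sum(sizes))) return(binarize(slice))
      marker <- lab == pickAnterior(lab)
      storage.mode(marker) <- "integer"
      # restore the eroded boundary: one conditional dilation with the same
      # structuring element, clipped to the original foreground
      restored <- (EBImage::dilate(marker, brush) > 0) & (fg > 0)
      labR <- EBImage::bwlabel(restored)
      keepId <- unique(labR[marker > 0])
      keepId <- keepId[keepId > 0]
      body <- matrix(labR %in% keepId, nrow(fg), ncol(fg))
      out <- matrix(0L, nrow(fg), ncol(fg)); out[body] <- 255L
      return(new("VertebraMask2D", mask = out, spacing = slice@spacing,
                 anteriorLow = anterior))
    }
  }
  # never split within the cap: treat as body-only
  binarize(slice)
}

#' Approximate the body contour by a four-vertex polygon
#'
#' Traces the outer contour of the (single) foreground component and
#' simplifies it by recursive farthest-point (Ramer-Douglas-Peucker)
#' reduction, binary-searching the tolerance down to the smallest value
#' that yields exactly four vertices; the vertices are then sharpened to
#' the maximum-area inscribed quadrilateral. With \code{subpixel = TRUE}
#' (the default) each corner is further refined to the intersection of
#' robust total-least-squares line fits of its two adjacent contour edges
#' (endplate concavities and corner rounding are trimmed as outliers),
#' which removes the half-pixel inward bias of rasterized corners; corners
#' of axis-aligned rectangles are returned exactly. All distances used in
#' the simplification are physical (mm), so anisotropic spacing does not
#' distort corner angles.
#'
#' @param mask a \linkS4class{VertebraMask2D} with one foreground component
#'   of at least 16 pixels.
#' @param subpixel refine corners to subpixel precision (set FALSE to get
#'   raw contour pixels).
#' @return 4 x 2 matrix of (row, col) vertices in contour order.
#' @export
approximateQuadrilateral <- function(mask, subpixel = TRUE) {
  stopifnot(is(mask, "VertebraMask2D"))
  fg <- mask@mask > 0
  lab <- EBImage::bwlabel(fg)
  if (max(lab) != 1L)
    stop("mask must contain exactly one foreground component")
  if (sum(fg) < 16L)
    stop("foreground too small (< 16 pixels) for polygon approximation")
  contour <- EBImage::ocontour(lab)[[1]] + 1  # 1-based (row, col)
  # simplify in physical coordinates so anisotropic spacing does not
  # distort corner angles; returned vertices are contour pixels
  mmPts <- sweep(contour, 2, mask@spacing, "*")

  nverts <- function(eps) length(.rdpClosed(mmPts, eps))
  diam <- sqrt(sum(((apply(mmPts, 2, max) - apply(mmPts, 2, min)))^2))
  lo <- 0; hi <- diam
  if (nverts(0) < 4L)
    stop("approximation-failure error: contour has fewer than 4 vertices")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (nverts(mid) > 4L) lo <- mid else hi <- mid
  }
  idx <- .rdpClosed(mmPts, hi)
  if (length(idx) != 4L) {
    # rare non-monotone jump past 4: scan down from hi
    for (eps in seq(hi, lo, length.out = 50L)) {
      idx <- .rdpClosed(mmPts, eps)
      if (length(idx) == 4L) break
    }
    if (length(idx) != 4L)
      stop("approximation-failure error: no tolerance yields 4 vertices")
  }
  # sharpen corner localization: move each vertex to the contour pixel that
  # maximizes the inscribed quadrilateral area (seeded by the RDP solution)
  idx <- .maxAreaQuad(mmPts, idx)
  v <- unname(contour[idx, , drop = FALSE])
  if (subpixel) {
    vs <- .subpixelCorners(contour, mmPts, idx, mask@spacing)
    if (!is.null(vs)) {
      # per corner, keep whichever candidate reaches farther out: the pixel
      # vertex is exact when the edges run through pixel centers, the
      # line-intersection vertex when rasterization rounds the corner off
      ctrMM <- colMeans(sweep(v, 2, mask@spacing, "*"))
      for (k in 1:4) {
        dPix <- .euclid(v[k, ] * mask@spacing, ctrMM)
        dSub <- .euclid(vs[k, ] * mask@spacing, ctrMM)
        if (dSub > dPix) v[k, ] <- vs[k, ]
      }
    }
  }
  v
}

# Robust total-least-squares line through 2D points: iteratively trims
# outliers (concavity arcs, rounded corner pixels) by perpendicular
# residual, then repositions the line as a support line through the
# outermost inlier (mask pixel centers lie inside the true edge, so the
# outermost one is the least biased; for edges running exactly through
# pixel centers the support line is the true edge). `outDir` is any vector
# with a positive component along the outward normal.
.robustLine <- function(p, floorTol, outDir) {
  if (nrow(p) < 2) return(NULL)
  keep <- rep(TRUE, nrow(p))
  for (it in 1:4) {
    q <- p[keep, , drop = FALSE]
    if (nrow(q) < 2) return(NULL)
    ctr <- colMeans(q)
    sv <- svd(sweep(q, 2, ctr))
    dirv <- sv$v[, 1]
    normal <- c(-dirv[2], dirv[1])
    res <- drop(sweep(p, 2, ctr) %*% normal)
    thr <- max(2.5 * stats::mad(res[keep], center = 0), floorTol)
    newKeep <- abs(res) <= thr
    if (all(newKeep == keep)) break
    keep <- newKeep
  }
  normal <- c(-dirv[2], dirv[1])
  if (sum(normal * outDir) < 0) normal <- -normal
  shift <- max(drop(sweep(p[keep, , drop = FALSE], 2, ctr) %*% normal))
  list(center = ctr + shift * normal, dir = dirv)
}

# Subpixel corners: intersect robust line fits of adjacent contour edges.
# Works in mm, returns pixel-unit coordinates; falls back to the pixel
# vertex where a fit or intersection is unreliable.
.subpixelCorners <- function(contour, mmPts, idx, spacing) {
  n <- nrow(contour)
  floorTol <- 0.45 * max(spacing)
  centroid <- colMeans(mmPts)
  lines <- vector("list", 4L)
  for (e in 1:4) {
    i <- idx[e]; j <- idx[e %% 4L + 1L]
    seg <- if (i < j) (i + 1L):(j - 1L) else c(if (i < n) (i + 1L):n, seq_len(max(0L, j - 1L)))
    if (length(seg) < 6L) return(NULL)
    # fit only the outer quarters of the edge: the middle may hold an
    # endplate concavity and the ends are rounded by rasterization
    rel <- seq_along(seg) / (length(seg) + 1)
    sel <- (rel >= 0.08 & rel <= 0.28) | (rel >= 0.72 & rel <= 0.92)
    if (sum(sel) < 4L) return(NULL)
    segPts <- mmPts[seg[sel], , drop = FALSE]
    lines[[e]] <- .robustLine(segPts, floorTol, colMeans(segPts) - centroid)
    if (is.null(lines[[e]])) return(NULL)
  }
  out <- matrix(NA_real_, 4L, 2L)
  for (v in 1:4) {
    l1 <- lines[[(v + 2L) %% 4L + 1L]]  # edge ending at vertex v
    l2 <- lines[[v]]                    # edge starting at vertex v
    A <- cbind(l1$dir, -l2$dir)
    if (abs(det(A)) < 1e-6) return(NULL)
    t <- solve(A, l2$center - l1$center)
    pt <- l1$center + t[1] * l1$dir
    pxPt <- pt / spacing
    if (.euclid(pxPt * spacing, mmPts[idx[v], ]) > 2.5 * max(spacing))
      pxPt <- contour[idx[v], ]
    out[v, ] <- pxPt
  }
  out
}

# Coordinate-descent refinement of 4 contour indices toward the
# maximum-area inscribed quadrilateral (indices kept in contour order).
.maxAreaQuad <- function(pts, idx, maxIter = 10L) {
  cross <- function(u, w) u[1] * w[2] - u[2] * w[1]
  for (it in seq_len(maxIter)) {
    changed <- FALSE
    for (v in 1:4) {
      p <- pts[idx[(v + 2L) %% 4L + 1L], ]  # previous vertex (cyclic)
      n <- pts[idx[v %% 4L + 1L], ]         # next vertex
      q <- pts[idx[(v + 1L) %% 4L + 1L], ]  # opposite vertex
      # shoelace area with vertex v free is affine in its coordinates
      C <- cross(n, q) + cross(q, p)
      A <- C + pts[, 2] * (p[1] - n[1]) + pts[, 1] * (n[2] - p[2])
      best <- which.max(abs(A))
      if (best != idx[v]) {
        idx[v] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(idx)
}

#' Label four polygon vertices as anatomical corners
#'
#' Assigns AS/PS/AI/PI so that superior corners lie above (smaller row
#' than) inferior ones and anterior corners at lower columns when
#' \code{anteriorLow} is TRUE (higher otherwise). The vertices are taken in
#' their cyclic order around the quadrilateral and the corner assignment
#' with the largest combined superior-above / anterior-in-front margin is
#' chosen, which reduces to "two lowest rows are superior, lower column is
#' anterior" for un-rotated bodies but stays correct for rotated ones.
#'
#' @param vertices 4 x 2 matrix of (row, col) points.
#' @param anteriorLow orientation flag.
#' @return a \linkS4class{LandmarkSet} with corners set and \code{CS},
#'   \code{CI} still \code{NA}.
#' @export
labelCorners <- function(vertices, anteriorLow = TRUE) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != 4L || nrow(unique(vertices)) != 4L)
    stop("degenerate-quadrilateral error: need 4 distinct vertices")
  combs <- utils::combn(4, 3)
  for (k in seq_len(ncol(combs))) {
    p <- vertices[combs[, k], ]
    if (abs(.polyArea(p)) < 1e-9)
      stop("degenerate-quadrilateral error: three vertices are collinear")
  }
  # cyclic order around the centroid
  ctr <- colMeans(vertices)
  ordc <- order(atan2(vertices[, 2] - ctr[2], vertices[, 1] - ctr[1]))
  v <- vertices[ordc, , drop = FALSE]
  s <- if (anteriorLow) 1 else -1
  best <- NULL; bestScore <- -Inf
  for (dir in list(1:4, 4:1)) for (k in 0:3) {
    idx <- dir[((0:3 + k) %% 4) + 1]   # (AS, PS, PI, AI) in cyclic order
    a <- v[idx[1], ]; p <- v[idx[2], ]; pi <- v[idx[3], ]; ai <- v[idx[4], ]
    score <- (ai[1] + pi[1] - a[1] - p[1]) +
      s * (p[2] + pi[2] - a[2] - ai[2])
    if (score > bestScore) {
      bestScore <- score
      best <- list(AS = a, PS = p, PI = pi, AI = ai)
    }
  }
  new("LandmarkSet", AS = best$AS, PS = best$PS, AI = best$AI, PI = best$PI,
      CS = c(NA_real_, NA_real_), CI = c(NA_real_, NA_real_))
}

#' Locate the central endplate landmarks by Bresenham midpoint search
#'
#' Rounds the midpoints of the superior (AS--PS) and inferior (AI--PI)
#' corner pairs to pixels, rasterizes the segment between them with
#' Bresenham's algorithm, and walks it from each end: the first foreground
#' pixel from the superior end is \code{CS}, the first from the inferior end
#' is \code{CI}. On a convex body the midpoints themselves are returned; on
#' a biconcave body the landmarks move inward past the endplate concavity.
#'
#' @param mask a \linkS4class{VertebraMask2D}.
#' @param corners a \linkS4class{LandmarkSet} with labeled corners.
#' @return the corners with \code{CS} and \code{CI} filled in.
#' @export
centralLandmarks <- function(mask, corners) {
  stopifnot(is(mask, "VertebraMask2D"), is(corners, "LandmarkSet"))
  m <- mask@mask
  mSup <- roundHalfUp((corners@AS + corners@PS) / 2)
  mInf <- roundHalfUp((corners@AI + corners@PI) / 2)
  path <- bresenhamLine(mSup, mInf)
  inGrid <- path[, 1] >= 1 & path[, 1] <= nrow(m) &
    path[, 2] >= 1 & path[, 2] <= ncol(m)
  on <- logical(nrow(path))
  for (k in seq_len(nrow(path)))
    on[k] <- inGrid[k] && m[path[k, 1], path[k, 2]] > 0
  if (!any(on))
    stop("central-landmark-failure error: no foreground pixel along the midpoint segment")
  cs <- path[which(on)[1], ]
  ci <- path[rev(which(on))[1], ]
  methods::initialize(corners, CS = as.numeric(cs), CI = as.numeric(ci))
}

#' Compute anterior, posterior and central heights from landmarks
#'
#' Each pixel displacement is scaled per axis by the pixel spacing before
#' taking the Euclidean norm: \code{Ha = |AS - AI|}, \code{Hp = |PS - PI|},
#' \code{Hc = |CS - CI|}, all in mm.
#'
#' @param landmarks a complete \linkS4class{LandmarkSet}.
#' @param spacing numeric(2) (row, col) spacing in mm.
#' @return named numeric: \code{Ha}, \code{Hp}, \code{Hc} (mm).
#' @export
computeHeights <- function(landmarks, spacing) {
  stopifnot(is(landmarks, "LandmarkSet"), length(spacing) == 2)
  dist <- function(a, b) sqrt(sum(((a - b) * spacing)^2))
  h <- c(Ha = dist(landmarks@AS, landmarks@AI),
         Hp = dist(landmarks@PS, landmarks@PI),
         Hc = dist(landmarks@CS, landmarks@CI))
  if (any(!is.finite(h)) || any(h <= 0))
    stop("degenerate-landmark error: heights must be finite and positive")
  h
}

#' Run the full landmark chain on one body mask
#'
#' Convenience wrapper: polygon approximation, corner labeling, central
#' landmark search and height computation.
#'
#' @param mask a \linkS4class{VertebraMask2D} containing only the vertebral
#'   body.
#' @return list with \code{landmarks} (\linkS4class{LandmarkSet}) and
#'   \code{heights} (named numeric, mm).
#' @export
extractHeights <- function(mask) {
  v <- approximateQuadrilateral(mask)
  lm <- labelCorners(v, anteriorLow = mask@anteriorLow)
  lm <- centralLandmarks(mask, lm)
  list(landmarks = lm, heights = computeHeights(lm, mask@spacing))
}
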