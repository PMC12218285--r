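# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero (round-half-up for positive values); base round()
# uses banker's rounding, which would make midpoint pixels spacing-dependent.
roundHalfUp <- function(x) floor(x + 0.5)

#' Rasterize a straight line between two pixels with Bresenham's algorithm
#'
#' Classic integer line-drawing: returns every pixel of the 8-connected
#' digital segment from \code{p0} to \code{p1}, endpoints included and in
#' order. Used to search for central endplate landmarks along the
#' superior--inferior midpoint segment.
#'
#' @param p0,p1 integer (row, col) pixel coordinates.
#' @return integer matrix with columns \code{row}, \code{col}.
#' @export
#' @examples
#' bresenhamLine(c(1, 1), c(4, 9))
bresenhamLine <- function(p0, p1) {
  p0 <- as.integer(round(p0)); p1 <- as.integer(round(p1))
  x0 <- p0[1]; y0 <- p0[2]; x1 <- p1[1]; y1 <- p1[2]
  dx <- abs(x1 - x0); sx <- if (x0 < x1) 1L else -1L
  dy <- -abs(y1 - y0); sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  out <- matrix(NA_integer_, nrow = dx - dy + 1L, ncol = 2L)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(x0, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  colnames(out) <- c("row", "col")
  out[seq_len(k), , drop = FALSE]
}

# Perpendicular distance of points (n x 2) from the segment a--b.
.segDist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  t <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% ab) / len2))
  proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2])
  sqrt(rowSums((pts - proj)^2))
}

# Ramer-Douglas-Peucker simplification of an open polyline (n x 2 matrix).
# Returns indices of retained vertices (always includes both endpoints).
.rdpIndices <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .segDist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    w <- which.max(d)
    if (d[w] > eps) {
      k <- mid[w]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  which(keep)
}

# Simplify a CLOSED contour (n x 2, no repeated end point) at tolerance eps.
# Anchored at the two (approximately) most distant contour points, then each
# half is simplified independently; returns the indices of the retained
# vertices in contour order.
.rdpClosed <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(seq_len(n))
  # double-sweep diameter approximation
  d1 <- rowSums(sweep(pts, 2, pts[1, ])^2)
  a <- which.max(d1)
  d2 <- rowSums(sweep(pts, 2, pts[a, ])^2)
  b <- which.max(d2)
  i <- min(a, b); j <- max(a, b)
  half1 <- pts[i:j, , drop = FALSE]
  half2 <- pts[c(j:n, 1:i), , drop = FALSE]
  k1 <- .rdpIndices(half1, eps)
  k2 <- .rdpIndices(half2, eps)
  idx1 <- (i:j)[k1]
  idx2 <- c(j:n, 1:i)[k2]
  idx <- unique(c(idx1, idx2))
  # restore contour order starting from i
  ord <- order((idx - i) %% n)
  idx[ord]
}

# Signed area of a polygon (n x 2, not closed).
.polyArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Do segments p1-p2 and p3-p4 properly intersect (excluding shared endpoints)?
.segIntersect <- function(p1, p2, p3, p4) {
  cr <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cr(p3, p4, p1); d2 <- cr(p3, p4, p2)
  d3 <- cr(p1, p2, p3); d4 <- cr(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

# Is a 4-vertex polygon (rows in order) simple and non-degenerate?
.isSimpleQuad <- function(p) {
  if (nrow(unique(p)) < 4L) return(FALSE)
  if (abs(.polyArea(p)) < 1e-9) return(FALSE)
  # opposite edges must not cross: edges 1-2 vs 3-4, 2-3 vs 4-1
  if (.segIntersect(p[1, ], p[2, ], p[3, ], p[4, ])) return(FALSE)
  if (.segIntersect(p[2, ], p[3, ], p[4, ], p[1, ])) return(FALSE)
  TRUE
}

.euclid <- function(a, b) sqrt(sum((a - b)^2))
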