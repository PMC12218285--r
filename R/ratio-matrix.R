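# Pseudo-Jacobian intra-individual height-ratio matrices.

#' Spinal regions used for the 3 x 3 reduction
#'
#' @return named list of level index vectors: \code{T1-T9}, \code{T10-L1},
#'   \code{L2-L5}.
#' @export
spineRegions <- function() list(`T1-T9` = 1:9, `T10-L1` = 10:13, `L2-L5` = 14:17)

#' Per-subject vertebral height-ratio matrix
#'
#' Builds the N x N Pseudo-Jacobian matrix \code{J[i, j] = H_i / H_j} over
#' the 17 thoracolumbar levels from one subject's heights; absent levels are
#' masked with NA. Rows are the numerator, so entries below the diagonal are
#' caudal-over-cranial ratios.
#'
#' @param heights numeric vector of heights; either length 17 (NA for
#'   missing levels) or accompanied by \code{levels}.
#' @param levels integer levels matching \code{heights} when the vector does
#'   not cover all 17.
#' @param heightType label stored on the result.
#' @return a \linkS4class{RatioMatrix} with scope "subject".
#' @export
#' @examples
#' ratioValues(subjectRatioMatrix(c(10, 20), levels = c(1, 2)))[1:2, 1:2]
subjectRatioMatrix <- function(heights, levels = NULL, heightType = "Hp") {
  h <- rep(NA_real_, 17)
  if (is.null(levels)) {
    if (length(heights) != 17)
      stop("supply 17 heights or an explicit `levels` vector")
    h <- as.numeric(heights)
  } else h[levels] <- heights
  present <- !is.na(h)
  if (sum(present) < 2) stop("need >= 2 levels present")
  if (any(h[present] <= 0)) stop("heights must be positive")
  J <- outer(h, h, "/")   # diagonal is exactly 1 for present levels
  dimnames(J) <- list(levelLabels(), levelLabels())
  new("RatioMatrix", values = J, heightType = heightType,
      scope = "subject", present = present)
}

#' Cohort-mean height-ratio matrix
#'
#' Element-wise arithmetic mean of the per-subject ratio matrices over all
#' subjects of one sex (each cell averaged over the subjects with both
#' levels present); the diagonal is 1 by construction.
#'
#' @param cohort height records.
#' @param sex "male" or "female".
#' @param heightType height column.
#' @return a \linkS4class{RatioMatrix} with scope "cohort-mean".
#' @export
cohortMeanMatrix <- function(cohort, sex = c("male", "female"),
                             heightType = "Hp") {
  sex <- match.arg(sex)
  .checkCohort(cohort)
  sub <- cohort[cohort$sex == sex, ]
  if (!nrow(sub)) stop("empty group: no ", sex, " subjects")
  ids <- unique(sub$subject_id)
  acc <- matrix(0, 17, 17); cnt <- matrix(0L, 17, 17)
  anyPresent <- logical(17)
  for (id in ids) {
    s <- sub[sub$subject_id == id, ]
    if (nrow(s) < 2) next
    J <- ratioValues(subjectRatioMatrix(s[[heightType]], levels = s$level,
                                        heightType = heightType))
    ok <- !is.na(J)
    acc[ok] <- acc[ok] + J[ok]
    cnt <- cnt + ok
    anyPresent[unique(s$level)] <- TRUE
  }
  if (!any(cnt > 0)) stop("empty group: no subject has >= 2 levels")
  M <- acc / cnt
  M[cnt == 0] <- NA_real_
  dimnames(M) <- list(levelLabels(), levelLabels())
  new("RatioMatrix", values = M, heightType = heightType,
      scope = "cohort-mean", present = anyPresent)
}

#' Regional 3 x 3 reduction of a mean ratio matrix
#'
#' Entry (A, B) is the mean of the mean-matrix cells with row level in
#' region A and column level in region B (diagonal cells included when
#' A = B). Masked cells inside a region trigger the partial flag and are
#' skipped in the mean.
#'
#' @param meanMatrix a \linkS4class{RatioMatrix}.
#' @return a \linkS4class{RegionalMatrix}.
#' @export
regionalMatrix <- function(meanMatrix) {
  stopifnot(is(meanMatrix, "RatioMatrix"))
  V <- ratioValues(meanMatrix)
  regs <- spineRegions()
  out <- matrix(NA_real_, 3, 3, dimnames = list(names(regs), names(regs)))
  partial <- FALSE
  for (a in 1:3) for (b in 1:3) {
    block <- V[regs[[a]], regs[[b]]]
    if (anyNA(block)) partial <- TRUE
    out[a, b] <- mean(block, na.rm = TRUE)
  }
  new("RegionalMatrix", values = out, heightType = meanMatrix@heightType,
      partial = partial)
}

#' Sex comparison of intra-individual height ratios
#'
#' For each vertebral level (or region), every subject is summarized by the
#' mean of their ratio-matrix row over all partner levels (diagonal
#' excluded; for a region, all cells with row level inside the region), and
#' the male and female summaries are compared with a two-sided Welch t-test
#' (signed statistic, male minus female) or a Wilcoxon rank-sum test with
#' normal approximation.
#'
#' @param cohort height records.
#' @param heightType height column.
#' @param granularity "level" (17 rows) or "region" (3 rows).
#' @param method "t" (Welch) or "wilcoxon".
#' @return data.frame with columns \code{row}, \code{statistic}, \code{p},
#'   \code{flag}.
#' @export
ratioSexTest <- function(cohort, heightType = "Hp",
                         granularity = c("level", "region"),
                         method = c("t", "wilcoxon")) {
  granularity <- match.arg(granularity)
  method <- match.arg(method)
  .checkCohort(cohort)
  ids <- unique(cohort$subject_id)
  summaries <- lapply(ids, function(id) {
    s <- cohort[cohort$subject_id == id, ]
    if (nrow(s) < 2) return(NULL)
    J <- ratioValues(subjectRatioMatrix(s[[heightType]], levels = s$level))
    diag(J) <- NA
    if (granularity == "level") {
      v <- rowMeans(J, na.rm = TRUE)
      v[is.nan(v)] <- NA
    } else {
      v <- vapply(spineRegions(), function(rg)
        mean(J[rg, ], na.rm = TRUE), 0)
      v[is.nan(v)] <- NA
    }
    list(sex = s$sex[1], v = v)
  })
  summaries <- Filter(Negate(is.null), summaries)
  sexes <- vapply(summaries, `[[`, "", "sex")
  mat <- do.call(rbind, lapply(summaries, `[[`, "v"))
  labels <- if (granularity == "level") levelLabels() else names(spineRegions())
  do.call(rbind, lapply(seq_along(labels), function(i) {
    xm <- mat[sexes == "male", i]; xm <- xm[!is.na(xm)]
    xf <- mat[sexes == "female", i]; xf <- xf[!is.na(xf)]
    if (length(xm) < 2 || length(xf) < 2)
      return(data.frame(row = labels[i], statistic = NA_real_,
                        p = NA_real_, flag = "insufficient"))
    if (method == "t") {
      tt <- stats::t.test(xm, xf)
      data.frame(row = labels[i], statistic = unname(tt$statistic),
                 p = tt$p.value, flag = "ok")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xm, xf, correct = FALSE))
      n1 <- length(xm); n2 <- length(xf)
      z <- (wt$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      data.frame(row = labels[i], statistic = unname(z),
                 p = wt$p.value, flag = "ok")
    }
  }))
}
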