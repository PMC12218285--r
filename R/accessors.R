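#' Pixel matrix of a 2D mask
#'
#' @param x a \linkS4class{VertebraMask2D}.
#' @return integer matrix of 0/255 values.
#' @export
#' @rdname maskMatrix
setMethod("maskMatrix", "VertebraMask2D", function(x) x@mask)

#' Pixel or voxel spacing in mm
#'
#' @param x a \linkS4class{VertebraMask2D} or \linkS4class{VertebraMask3D}.
#' @return numeric spacing vector in mm, one entry per axis.
#' @export
#' @rdname pixelSpacing
setMethod("pixelSpacing", "VertebraMask2D", function(x) x@spacing)

#' @rdname pixelSpacing
#' @export
setMethod("pixelSpacing", "VertebraMask3D", function(x) x@spacing)

#' Orientation flag: is anterior at low column indices?
#'
#' @param x a \linkS4class{VertebraMask2D} or \linkS4class{VertebraMask3D}.
#' @return logical(1).
#' @export
#' @rdname anteriorLow
setMethod("anteriorLow", "VertebraMask2D", function(x) x@anteriorLow)

#' @rdname anteriorLow
#' @export
setMethod("anteriorLow", "VertebraMask3D", function(x) x@anteriorLow)

#' True heights of a synthetic mask
#'
#' @param x a \linkS4class{LandmarkTruth}.
#' @return named numeric: \code{Ha}, \code{Hp}, \code{Hc} in mm.
#' @export
#' @rdname trueHeights
setMethod("trueHeights", "LandmarkTruth", function(x)
  c(Ha = x@Ha, Hp = x@Hp, Hc = x@Hc))

#' True corner positions of a synthetic mask
#'
#' @param x a \linkS4class{LandmarkTruth}.
#' @return 4 x 2 matrix (AS, PS, AI, PI) in mm, raster frame.
#' @export
#' @rdname trueCorners
setMethod("trueCorners", "LandmarkTruth", function(x) x@corners)

#' Values of a ratio matrix
#'
#' @param x a \linkS4class{RatioMatrix} or \linkS4class{RegionalMatrix}.
#' @return the numeric ratio matrix (NA where masked).
#' @export
#' @rdname ratioValues
setMethod("ratioValues", "RatioMatrix", function(x) x@values)

#' @rdname ratioValues
#' @export
setMethod("ratioValues", "RegionalMatrix", function(x) x@values)

#' Fixed-effect estimates of a fitted spline model
#'
#' @param x a \linkS4class{MixedFit}.
#' @return named numeric vector of fixed-effect coefficients.
#' @export
#' @rdname fixedEffects
setMethod("fixedEffects", "MixedFit", function(x) x@coefficients)

#' Random-effect standard deviations
#'
#' @param x a \linkS4class{MixedFit}.
#' @return named numeric: \code{sdIntercept}, \code{sdSlope}, \code{corr},
#'   \code{sigma}.
#' @export
#' @rdname randomEffectSD
setMethod("randomEffectSD", "MixedFit", function(x)
  c(x@ranefSD, sigma = x@sigma))

#' Fit criteria of a model
#'
#' @param x a \linkS4class{MixedFit}.
#' @return named numeric: \code{logLik}, \code{df}, \code{AIC}, \code{BIC},
#'   \code{nObs}.
#' @export
#' @rdname fitCriteria
setMethod("fitCriteria", "MixedFit", function(x)
  c(logLik = x@logLik, df = x@df, AIC = x@AIC, BIC = x@BIC, nObs = x@nObs))

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition R-squared: the marginal value is the share of
#' total variance (fixed + random + residual) attributable to the fixed
#' effects; the conditional value adds the random-effect variance to the
#' numerator.
#'
#' @param x a \linkS4class{MixedFit}.
#' @return named numeric: \code{R2marginal}, \code{R2conditional}.
#' @export
#' @rdname r2Nakagawa
setMethod("r2Nakagawa", "MixedFit", function(x) {
  tot <- x@varFixed + x@varRandom + x@varResidual
  if (tot <= 0) stop("zero total variance: R-squared undefined")
  c(R2marginal = x@varFixed / tot,
    R2conditional = (x@varFixed + x@varRandom) / tot)
})

setMethod("show", "VertebraMask2D", function(object) {
  cat(sprintf("VertebraMask2D: %d x %d pixels, spacing (%.3g, %.3g) mm, %d foreground px, anteriorLow=%s\n",
              nrow(object@mask), ncol(object@mask),
              object@spacing[1], object@spacing[2],
              sum(object@mask > 0), object@anteriorLow))
})

setMethod("show", "VertebraMask3D", function(object) {
  d <- dim(object@volume)
  cat(sprintf("VertebraMask3D: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, labels: %s, sagittal axis %d\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3],
              paste(sort(unique(object@volume[object@volume > 0])), collapse = ","),
              object@sagittalAxis))
})

setMethod("show", "LandmarkSet", function(object) {
  fmt <- function(p) if (any(is.na(p))) "NA" else sprintf("(%g, %g)", p[1], p[2])
  cat("LandmarkSet (row, col):\n",
      sprintf("  AS %s  PS %s\n", fmt(object@AS), fmt(object@PS)),
      sprintf("  CS %s  CI %s\n", fmt(object@CS), fmt(object@CI)),
      sprintf("  AI %s  PI %s\n", fmt(object@AI), fmt(object@PI)))
})

setMethod("show", "LandmarkTruth", function(object) {
  cat(sprintf("LandmarkTruth: Ha = %.4f, Hp = %.4f, Hc = %.4f mm\n",
              object@Ha, object@Hp, object@Hc))
})

setMethod("show", "MixedFit", function(object) {
  cat(sprintf("MixedFit (%s basis, %s random effects) for %s\n",
              object@basis, object@randomEffects, object@heightType))
  cat(sprintf("  knots: %s; nObs = %d, subjects = %d\n",
              if (length(object@knots)) paste(object@knots, collapse = ", ") else "none",
              object@nObs, object@nSubjects))
  cat("  fixed effects:\n")
  print(round(object@coefficients, 4))
  cat(sprintf("  sigma = %.4f; AIC = %.2f, BIC = %.2f; R2m = %.3f, R2c = %.3f\n",
              object@sigma, object@AIC, object@BIC,
              object@R2marginal, object@R2conditional))
})

setMethod("show", "RatioMatrix", function(object) {
  cat(sprintf("RatioMatrix (%s, %s): %d levels present\n",
              object@heightType, object@scope, sum(object@present)))
  v <- object@values
  cat(sprintf("  range of present ratios: [%.3f, %.3f]\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "RegionalMatrix", function(object) {
  cat(sprintf("RegionalMatrix (%s)%s:\n", object@heightType,
              if (object@partial) " [partial]" else ""))
  print(round(object@values, 4))
})

setMethod("show", "MaskSpec", function(object) {
  cat(sprintf("MaskSpec: Ha0 = %.3f, Hp0 = %.3f mm; concavity (%.2f, %.2f) mm; rotation %.1f deg; spacing (%.2f, %.2f) mm; noise SD %.2f mm\n",
              .euclid(object@cornerAS, object@cornerAI),
              .euclid(object@cornerPS, object@cornerPI),
              object@concavitySuperior, object@concavityInferior,
              object@rotation, object@spacing[1], object@spacing[2],
              object@boundaryNoiseSD))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: n = %d (%.0f%% male); SDs: intercept %.2f, slope %.3f, residual %.2f mm; seed %d\n",
              object@nSubjects, 100 * object@sexRatio, object@sdIntercept,
              object@sdSlope, object@sdResidual, object@seed))
})
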