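#' @import methods
NULL

#' Geometric specification of a synthetic vertebral body mask
#'
#' Describes one vertebral body in continuous (mm) coordinates: the four
#' corners of the body quadrilateral, the central depths of the superior and
#' inferior endplate concavities, an in-plane rotation, the pixel spacing of
#' the target raster, and the standard deviation of boundary jitter.
#' Coordinates are (row, col) with rows increasing caudally
#' (superior to inferior) and columns increasing posteriorly
#' (anterior at low columns).
#'
#' @slot cornerAS,cornerPS,cornerAI,cornerPI numeric(2), corner positions in
#'   mm: anterior-superior, posterior-superior, anterior-inferior,
#'   posterior-inferior.
#' @slot concavitySuperior,concavityInferior central endplate concavity depth
#'   in mm (>= 0), modeled as a circular-segment bite centered at the edge
#'   midpoint.
#' @slot rotation in-plane rotation in degrees applied about the centroid.
#' @slot spacing numeric(2), (row, col) pixel spacing in mm (> 0).
#' @slot boundaryNoiseSD SD (mm) of independent normal contour jitter.
#' @export
setClass("MaskSpec", representation(
  cornerAS = "numeric", cornerPS = "numeric",
  cornerAI = "numeric", cornerPI = "numeric",
  concavitySuperior = "numeric", concavityInferior = "numeric",
  rotation = "numeric", spacing = "numeric", boundaryNoiseSD = "numeric"
))

setValidity("MaskSpec", function(object) {
  msg <- character()
  pts <- rbind(object@cornerAS, object@cornerPS, object@cornerPI, object@cornerAI)
  if (ncol(pts) != 2 || any(!is.finite(pts)))
    msg <- c(msg, "corners must be finite 2D points")
  else if (!.isSimpleQuad(pts))
    msg <- c(msg, "corners must form a simple, non-degenerate quadrilateral")
  if (any(c(object@concavitySuperior, object@concavityInferior) < 0))
    msg <- c(msg, "concavity depths must be >= 0")
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive values (row_mm, col_mm)")
  if (object@boundaryNoiseSD < 0)
    msg <- c(msg, "boundaryNoiseSD must be >= 0")
  if (!length(msg)) {
    edgeA <- .euclid(object@cornerAS, object@cornerAI)
    edgeP <- .euclid(object@cornerPS, object@cornerPI)
    lim <- min(edgeA, edgeP) / 2
    if (object@concavitySuperior >= lim || object@concavityInferior >= lim)
      msg <- c(msg, "concavity depth must be < half the smaller of the anterior/posterior edge lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Binary 2D vertebral body mask
#'
#' A single midsagittal vertebral body mask after binarization: a 0/255
#' integer matrix with (row, col) pixel spacing in mm and an orientation flag
#' saying whether anterior is at low column indices.
#'
#' @slot mask integer matrix with values 0 and 255.
#' @slot spacing numeric(2), (row_mm, col_mm) pixel spacing.
#' @slot anteriorLow logical; TRUE when anterior is at low columns.
#' @export
setClass("VertebraMask2D", representation(
  mask = "matrix", spacing = "numeric", anteriorLow = "logical"
))

setValidity("VertebraMask2D", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0, 255)))
    msg <- c(msg, "mask values must be 0 or 255 (use binarize())")
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive values")
  if (length(object@anteriorLow) != 1)
    msg <- c(msg, "anteriorLow must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Labeled 3D vertebral segmentation volume
#'
#' An integer-labeled voxel grid (one positive label per vertebral level,
#' 0 = background) with voxel spacing and explicit axis roles: by default
#' axis 1 runs cranio-caudally, axis 2 antero-posteriorly, and axis 3 is the
#' sagittal (left-right) axis along which the midsagittal slice is chosen.
#'
#' @slot volume 3D integer array of labels.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot sagittalAxis which array axis is left-right (1, 2 or 3).
#' @slot anteriorLow logical orientation flag for the extracted 2D slices.
#' @export
setClass("VertebraMask3D", representation(
  volume = "array", spacing = "numeric", sagittalAxis = "integer",
  anteriorLow = "logical"
))

setValidity("VertebraMask3D", function(object) {
  msg <- character()
  if (length(dim(object@volume)) != 3)
    msg <- c(msg, "volume must be a 3D array")
  if (any(object@volume < 0))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (!object@sagittalAxis %in% 1:3)
    msg <- c(msg, "sagittalAxis must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Landmark set of one vertebral body
#'
#' The four labeled corner pixels (anterior/posterior x superior/inferior)
#' plus the two central endplate landmarks found by the Bresenham midpoint
#' search, all in (row, col) pixel coordinates. \code{CS}/\code{CI} may be
#' \code{NA} before \code{\link{centralLandmarks}} has been run.
#'
#' @slot AS,PS,AI,PI numeric(2) corner pixels.
#' @slot CS,CI numeric(2) central superior/inferior endplate pixels.
#' @export
setClass("LandmarkSet", representation(
  AS = "numeric", PS = "numeric", AI = "numeric", PI = "numeric",
  CS = "numeric", CI = "numeric"
))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  for (nm in c("AS", "PS", "AI", "PI", "CS", "CI"))
    if (length(slot(object, nm)) != 2)
      msg <- c(msg, sprintf("%s must have length 2", nm))
  if (!length(msg)) {
    if (!(object@AS[1] < object@AI[1] && object@PS[1] < object@PI[1]))
      msg <- c(msg, "superior corners must have smaller row than inferior corners")
  }
  if (length(msg)) msg else TRUE
})

#' Continuous-space ground truth for a synthetic mask
#'
#' Exact corner and central endplate positions (mm, in the raster frame of
#' the generated mask) together with the true anterior, posterior and
#' central heights, as constructed by \code{\link{makeVertebraMask}}.
#'
#' @slot corners 4 x 2 matrix (rows AS, PS, AI, PI) in mm.
#' @slot centralSuperior,centralInferior numeric(2) in mm.
#' @slot Ha,Hp,Hc true heights in mm.
#' @export
setClass("LandmarkTruth", representation(
  corners = "matrix", centralSuperior = "numeric", centralInferior = "numeric",
  Ha = "numeric", Hp = "numeric", Hc = "numeric"
))

#' Generative specification of a synthetic height cohort
#'
#' Parameters of the height simulator: cohort size and sex ratio, the
#' per-level per-sex mean curves for the three height types, the SDs of the
#' per-subject random intercept and slope and of the residual, and a seed.
#'
#' @slot nSubjects number of subjects.
#' @slot sexRatio fraction of male subjects in [0, 1].
#' @slot meanCurve numeric array [17 levels x 2 sexes x 3 height types] of
#'   mean heights in mm; dimnames sexes \code{male}/\code{female}, types
#'   \code{Ha}/\code{Hp}/\code{Hc}.
#' @slot sdIntercept,sdSlope,sdResidual standard deviations in mm (slope in
#'   mm per level) of the random intercept, random slope and residual.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "numeric", sexRatio = "numeric", meanCurve = "array",
  sdIntercept = "numeric", sdSlope = "numeric", sdResidual = "numeric",
  seed = "numeric"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@sexRatio < 0 || object@sexRatio > 1)
    msg <- c(msg, "sexRatio must be in [0, 1]")
  d <- dim(object@meanCurve)
  if (length(d) != 3 || d[1] != 17 || d[2] != 2 || d[3] != 3)
    msg <- c(msg, "meanCurve must be a 17 x 2 x 3 array (levels T1..L5, sexes, Ha/Hp/Hc)")
  if (any(c(object@sdIntercept, object@sdSlope, object@sdResidual) < 0))
    msg <- c(msg, "all SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Fitted mixed-effects spline model
#'
#' Container for one fitted vertebral-height regression: fixed coefficients,
#' random-effect SDs, variance decomposition, fit criteria and marginal/
#' conditional R-squared. Created by \code{\link{fitMixedSpline}} and
#' \code{\link{fitLinearSpline}}.
#'
#' @slot heightType which height was modeled ("Ha", "Hp" or "Hc").
#' @slot basis "cubic" or "linear" truncated-power basis.
#' @slot knots interior knot positions on the 1..17 level axis.
#' @slot coefficients named fixed-effect estimates.
#' @slot seFixed standard errors of the fixed effects.
#' @slot ranefSD named SDs of the random intercept/slope and their
#'   correlation (NA where absent).
#' @slot sigma residual SD.
#' @slot varFixed,varRandom,varResidual variance decomposition used for the
#'   marginal/conditional R-squared.
#' @slot logLik,df,AIC,BIC,nObs,nSubjects fit criteria and sizes.
#' @slot R2marginal,R2conditional variance explained by fixed effects alone
#'   and by fixed plus random effects.
#' @slot randomEffects "correlated", "independent" or "none".
#' @slot dataSignature internal checksum used to verify that compared models
#'   were fitted on identical data.
#' @slot model the underlying \code{lmerMod}/\code{lm} fit.
#' @export
setClass("MixedFit", representation(
  heightType = "character", basis = "character", knots = "numeric",
  coefficients = "numeric", seFixed = "numeric", ranefSD = "numeric",
  sigma = "numeric", varFixed = "numeric", varRandom = "numeric",
  varResidual = "numeric", logLik = "numeric", df = "numeric",
  AIC = "numeric", BIC = "numeric", nObs = "numeric", nSubjects = "numeric",
  R2marginal = "numeric", R2conditional = "numeric",
  randomEffects = "character", dataSignature = "numeric", model = "ANY"
))

setValidity("MixedFit", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (is.finite(object@R2marginal) && is.finite(object@R2conditional) &&
      object@R2marginal > object@R2conditional + 1e-8)
    msg <- c(msg, "marginal R2 cannot exceed conditional R2")
  if (length(msg)) msg else TRUE
})

#' Intra-individual vertebral height-ratio (Pseudo-Jacobian) matrix
#'
#' An N x N matrix of pairwise vertebral height ratios
#' \code{J[i, j] = H_i / H_j} over the 17 thoracolumbar levels, either for
#' one subject or as an element-wise cohort mean; missing levels are masked
#' with \code{NA}.
#'
#' @slot values 17 x 17 numeric matrix.
#' @slot heightType "Ha", "Hp" or "Hc".
#' @slot scope "subject", "cohort-mean" or "regional".
#' @slot present logical(17), which levels are present.
#' @export
setClass("RatioMatrix", representation(
  values = "matrix", heightType = "character", scope = "character",
  present = "logical"
))

setValidity("RatioMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (!object@scope %in% c("subject", "cohort-mean", "regional"))
    msg <- c(msg, "scope must be subject, cohort-mean or regional")
  if (object@scope == "subject" && nrow(v) == 17) {
    dg <- diag(v)[object@present]
    if (length(dg) && any(dg != 1))
      msg <- c(msg, "subject-scope diagonal must be exactly 1")
  }
  if (length(msg)) msg else TRUE
})

#' Regional 3 x 3 reduction of a ratio matrix
#'
#' Mean height ratios over the three spinal regions T1-T9, T10-L1 and L2-L5,
#' matching the segmentation used by the spline regression.
#'
#' @slot values 3 x 3 numeric matrix with region dimnames.
#' @slot heightType "Ha", "Hp" or "Hc".
#' @slot partial logical; TRUE when some cells were averaged over an
#'   incomplete region.
#' @export
setClass("RegionalMatrix", representation(
  values = "matrix", heightType = "character", partial = "logical"
))
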