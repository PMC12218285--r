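#' @rdname maskMatrix
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname pixelSpacing
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname anteriorLow
#' @export
setGeneric("anteriorLow", function(x) standardGeneric("anteriorLow"))

#' @rdname trueHeights
#' @export
setGeneric("trueHeights", function(x) standardGeneric("trueHeights"))

#' @rdname trueCorners
#' @export
setGeneric("trueCorners", function(x) standardGeneric("trueCorners"))

#' @rdname ratioValues
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))

#' @rdname fixedEffects
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname randomEffectSD
#' @export
setGeneric("randomEffectSD", function(x) standardGeneric("randomEffectSD"))

#' @rdname fitCriteria
#' @export
setGeneric("fitCriteria", function(x) standardGeneric("fitCriteria"))

#' @rdname r2Nakagawa
#' @export
setGeneric("r2Nakagawa", function(x) standardGeneric("r2Nakagawa"))
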