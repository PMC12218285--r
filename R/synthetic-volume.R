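#' Generate a labeled 3D spine segmentation volume
#'
#' Stacks one synthetic vertebra per level cranio-caudally. Each level is a
#' rasterized vertebral body (from its \linkS4class{MaskSpec}) extruded over
#' several sagittal slices, plus a smaller posterior-process blob connected
#' to the body by a thin bridge -- mimicking a whole-vertebra segmentation
#' label. Axis order is (cranio-caudal, antero-posterior, left-right); the
#' sagittal axis is 3.
#'
#' @param nLevels number of vertebral levels (1..17).
#' @param specs a single \linkS4class{MaskSpec} recycled to all levels, or a
#'   list of one spec per level.
#' @param seed integer seed (drives any boundary jitter in the specs).
#' @param bodySlices,processSlices number of sagittal slices spanned by the
#'   body and by the posterior process (process must be thinner).
#' @param gap background rows inserted between consecutive levels.
#' @return a \linkS4class{VertebraMask3D} with labels 1..nLevels.
#' @export
makeSpineVolume <- function(nLevels, specs, seed = NULL,
                            bodySlices = 7L, processSlices = 3L, gap = 2L) {
  if (is(specs, "MaskSpec")) specs <- rep(list(specs), nLevels)
  if (!length(specs)) stop("invalid-spec error: empty spec list")
  if (nLevels < 1 || nLevels > 17) stop("nLevels must be in 1..17")
  if (length(specs) != nLevels)
    stop("specs must have one entry per level (or a single MaskSpec)")
  if (processSlices >= bodySlices)
    stop("posterior process must span fewer slices than the body")

  slices <- lapply(seq_len(nLevels), function(l) {
    res <- makeVertebraMask(specs[[l]], seed = if (is.null(seed)) NULL else seed + l)
    m <- maskMatrix(res$mask) > 0
    # posterior process: disc behind the body, connected by a 2-px bridge
    fgCols <- which(colSums(m) > 0)
    fgRows <- which(rowSums(m) > 0)
    midRow <- round(mean(range(fgRows)))
    lastCol <- max(fgCols)
    procR <- max(3L, round(length(fgRows) / 5))
    bridgeLen <- 4L
    procCtr <- c(midRow, lastCol + bridgeLen + procR)
    nc2 <- procCtr[2] + procR + 3L
    full <- matrix(FALSE, nrow(m), max(ncol(m), nc2))
    full[, seq_len(ncol(m))] <- m
    # bridge: 2 px thick
    bodyEdge <- max(which(m[midRow, ] | m[midRow + 1L, ]))
    full[midRow + 0:1, bodyEdge:(procCtr[2])] <- TRUE
    rr <- matrix(seq_len(nrow(full)), nrow(full), ncol(full))
    cc <- matrix(seq_len(ncol(full)), nrow(full), ncol(full), byrow = TRUE)
    full[(rr - procCtr[1])^2 + (cc - procCtr[2])^2 <= procR^2] <- TRUE
    list(body = m, full = full)
  })

  nrTot <- sum(vapply(slices, function(s) nrow(s$full), 1L)) +
    gap * (nLevels - 1L)
  ncTot <- max(vapply(slices, function(s) ncol(s$full), 1L))
  ns <- bodySlices + 4L
  vol <- array(0L, dim = c(nrTot, ncTot, ns))
  sagMid <- (ns + 1L) %/% 2L
  bodyIdx <- sagMid + seq_len(bodySlices) - (bodySlices + 1L) %/% 2L
  procIdx <- sagMid + seq_len(processSlices) - (processSlices + 1L) %/% 2L

  rowOff <- 0L
  for (l in seq_len(nLevels)) {
    s <- slices[[l]]
    ri <- rowOff + seq_len(nrow(s$full))
    for (k in bodyIdx) {
      sub <- vol[ri, seq_len(ncol(s$full)), k]
      sub[if (k %in% procIdx) s$full else
            cbind(matrix(FALSE, nrow(s$body), 0), s$body,
                  matrix(FALSE, nrow(s$body), ncol(s$full) - ncol(s$body)))] <- l
      vol[ri, seq_len(ncol(s$full)), k] <- sub
    }
    rowOff <- rowOff + nrow(s$full) + gap
  }

  sp <- specs[[1]]@spacing
  new("VertebraMask3D", volume = vol,
      spacing = c(sp[1], sp[2], mean(sp)),
      sagittalAxis = 3L, anteriorLow = TRUE)
}
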