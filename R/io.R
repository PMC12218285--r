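# Reading and writing masks, cohorts and specs.

#' Write / read a labeled spine volume as NIfTI
#'
#' @param volume a \linkS4class{VertebraMask3D}.
#' @param path output .nii / .nii.gz path.
#' @return \code{writeSpineVolume} returns the path invisibly;
#'   \code{readSpineVolume} returns a \linkS4class{VertebraMask3D}.
#' @export
writeSpineVolume <- function(volume, path) {
  stopifnot(is(volume, "VertebraMask3D"))
  img <- RNifti::asNifti(volume@volume)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeSpineVolume
#' @param sagittalAxis which axis of the stored array is left-right.
#' @param anteriorLow orientation flag for extracted slices.
#' @export
readSpineVolume <- function(path, sagittalAxis = 3L, anteriorLow = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim = dim(img))
  new("VertebraMask3D", volume = arr,
      spacing = as.numeric(RNifti::pixdim(img))[1:3],
      sagittalAxis = as.integer(sagittalAxis), anteriorLow = anteriorLow)
}

#' Write / read a 2D mask as a plain-text grid
#'
#' Line 1 holds the metadata (\code{spacing <row> <col> anteriorLow <0/1>}),
#' the remaining lines the 0/255 pixel rows.
#'
#' @param mask a \linkS4class{VertebraMask2D}.
#' @param path text file path.
#' @return \code{writeMaskText} returns the path invisibly;
#'   \code{readMaskText} a \linkS4class{VertebraMask2D}.
#' @export
writeMaskText <- function(mask, path) {
  stopifnot(is(mask, "VertebraMask2D"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("spacing %.10g %.10g anteriorLow %d",
                     mask@spacing[1], mask@spacing[2],
                     as.integer(mask@anteriorLow)), con)
  utils::write.table(mask@mask, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeMaskText
#' @export
readMaskText <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " +")[[1]]
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  new("VertebraMask2D", mask = m,
      spacing = as.numeric(hdr[2:3]), anteriorLow = hdr[5] == "1")
}

#' Write / read a height cohort as CSV
#'
#' @param cohort height records data.frame.
#' @param path CSV path.
#' @export
writeCohortCSV <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkCohort(out)
}

#' Serialize / restore a mask specification as JSON
#'
#' @param spec a \linkS4class{MaskSpec}.
#' @param path JSON path.
#' @export
writeMaskSpecJSON <- function(spec, path) {
  stopifnot(is(spec, "MaskSpec"))
  x <- list(cornerAS = spec@cornerAS, cornerPS = spec@cornerPS,
            cornerAI = spec@cornerAI, cornerPI = spec@cornerPI,
            concavitySuperior = spec@concavitySuperior,
            concavityInferior = spec@concavityInferior,
            rotation = spec@rotation, spacing = spec@spacing,
            boundaryNoiseSD = spec@boundaryNoiseSD)
  jsonlite::write_json(x, path, digits = NA)
  invisible(path)
}

#' @rdname writeMaskSpecJSON
#' @export
readMaskSpecJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  maskSpec(x$cornerAS, x$cornerPS, x$cornerAI, x$cornerPI,
           concavitySuperior = x$concavitySuperior,
           concavityInferior = x$concavityInferior,
           rotation = x$rotation, spacing = x$spacing,
           boundaryNoiseSD = x$boundaryNoiseSD)
}
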