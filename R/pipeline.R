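# End-to-end orchestration: volumes -> heights -> report directory.

#' Extract heights from labeled spine volumes
#'
#' Runs the full mask-to-heights chain (midsagittal slice, posterior-element
#' removal, binarization, landmark extraction) for every label of every
#' volume. A vertebra that fails any stage is logged as an exclusion with
#' its error message rather than aborting the run; the returned tally
#' reconciles: total = analyzed + excluded, measurements = 3 x analyzed.
#'
#' @param volumes named list of \linkS4class{VertebraMask3D} (names are the
#'   subject ids), or a directory containing per-subject NIfTI volumes.
#' @param sexes optional named character vector of subject sexes.
#' @param outCsv optional path for the heights CSV.
#' @return list with \code{heights} (data.frame \code{subject_id},
#'   \code{sex}, \code{level}, \code{Ha}, \code{Hp}, \code{Hc},
#'   \code{qc_flag}), \code{exclusions} (data.frame of subject, level,
#'   reason), and \code{tally} (see \code{\link{exclusionTally}}).
#' @export
runExtraction <- function(volumes, sexes = NULL, outCsv = NULL) {
  if (is.character(volumes) && length(volumes) == 1 && dir.exists(volumes)) {
    files <- list.files(volumes, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    volumes <- lapply(files, readSpineVolume)
    names(volumes) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  }
  if (is(volumes, "VertebraMask3D")) volumes <- list(subject1 = volumes)
  if (is.null(names(volumes)))
    names(volumes) <- paste0("subject", seq_along(volumes))

  heights <- list(); exclusions <- list(); total <- 0L
  for (sid in names(volumes)) {
    vol <- volumes[[sid]]
    labels <- sort(unique(vol@volume[vol@volume > 0]))
    for (lab in labels) {
      total <- total + 1L
      res <- tryCatch({
        slice <- extractMidsagittalSlice(vol, lab)
        body <- removePosteriorElements(binarize(slice))
        extractHeights(body)$heights
      }, error = function(e) e)
      if (inherits(res, "error")) {
        exclusions[[length(exclusions) + 1L]] <-
          data.frame(subject_id = sid, level = lab,
                     reason = conditionMessage(res))
      } else {
        heights[[length(heights) + 1L]] <-
          data.frame(subject_id = sid,
                     sex = if (!is.null(sexes)) sexes[[sid]] else NA_character_,
                     level = lab, Ha = res[["Ha"]], Hp = res[["Hp"]],
                     Hc = res[["Hc"]], qc_flag = "ok")
      }
    }
  }
  heights <- if (length(heights)) do.call(rbind, heights) else
    data.frame(subject_id = character(), sex = character(),
               level = integer(), Ha = numeric(), Hp = numeric(),
               Hc = numeric(), qc_flag = character())
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(subject_id = character(), level = integer(),
               reason = character())
  if (!is.null(outCsv)) writeCohortCSV(heights, outCsv)
  list(heights = heights, exclusions = exclusions,
       tally = exclusionTally(total, nrow(exclusions)))
}

#' Run the full statistical analysis and assemble a report directory
#'
#' Sequences the cohort statistics over all three height types: sex delta
#' tables, wedge/biconcavity indices, per-level t-tests, the model
#' comparison (mixed cubic spline vs mixed linear spline vs ordinary least
#' squares), sex-wise mean ratio matrices with their regional reductions,
#' and the ratio sex tests. All tables are written as CSV into
#' \code{outDir} together with a JSON manifest and summary; reruns with the
#' same inputs and seed are byte-identical.
#'
#' @param cohort height records (or a heights CSV path).
#' @param outDir report directory (created if needed).
#' @param knots spline knots.
#' @param seed seed echoed into the report (the analysis itself is
#'   deterministic).
#' @param heightTypes height columns to analyze.
#' @return invisible list: \code{counts}, \code{files}, and the in-memory
#'   tables.
#' @export
runAnalysis <- function(cohort, outDir, knots = c(9, 13), seed = 1,
                        heightTypes = c("Ha", "Hp", "Hc")) {
  if (is.character(cohort)) cohort <- readCohortCSV(cohort)
  .checkCohort(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(x, name) {
    p <- file.path(outDir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, name)
    p
  }

  tables <- list()
  for (ht in heightTypes) {
    tables[[paste0("delta_", ht)]] <- sexDeltaTable(cohort, ht)
    emit(tables[[paste0("delta_", ht)]], sprintf("delta_%s.csv", ht))
    tables[[paste0("ttest_", ht)]] <- perLevelTest(cohort, ht)
    emit(tables[[paste0("ttest_", ht)]], sprintf("ttest_%s.csv", ht))

    fits <- list(
      mixed_cubic = fitMixedSpline(cohort, ht, knots = knots),
      mixed_linear = fitLinearSpline(cohort, ht, knots = knots),
      ols_cubic = fitMixedSpline(cohort, ht, knots = knots,
                                 randomEffects = "none"))
    cmp <- compareModels(fits)
    tables[[paste0("models_", ht)]] <- cmp
    emit(cmp, sprintf("models_%s.csv", ht))
    coefTab <- data.frame(term = names(fits$mixed_cubic@coefficients),
                          estimate = unname(fits$mixed_cubic@coefficients),
                          se = unname(fits$mixed_cubic@seFixed))
    emit(coefTab, sprintf("coefficients_%s.csv", ht))

    for (sx in c("male", "female")) {
      M <- cohortMeanMatrix(cohort, sx, ht)
      emit(as.data.frame(ratioValues(M)), sprintf("ratio_%s_%s.csv", ht, sx))
      emit(as.data.frame(ratioValues(regionalMatrix(M))),
           sprintf("ratio_regional_%s_%s.csv", ht, sx))
    }
    tables[[paste0("ratio_test_", ht)]] <-
      ratioSexTest(cohort, ht, granularity = "level")
    emit(tables[[paste0("ratio_test_", ht)]],
         sprintf("ratio_test_%s.csv", ht))
  }

  wb <- wedgeBiconcavity(cohort)
  emit(wb$means, "indices.csv")

  counts <- list(
    subjects = length(unique(cohort$subject_id)),
    males = length(unique(cohort$subject_id[cohort$sex == "male"])),
    females = length(unique(cohort$subject_id[cohort$sex == "female"])),
    records = nrow(cohort),
    measurements = 3L * nrow(cohort))
  summary <- list(counts = counts, seed = seed, knots = knots,
                  heightTypes = heightTypes,
                  version = as.character(utils::packageVersion("vertmorph")))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(files = sort(c(files, "summary.json"))),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts = counts, files = files, tables = tables))
}
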