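# Cohort-level descriptive and inferential statistics on height records.

.checkCohort <- function(cohort) {
  need <- c("subject_id", "sex", "level")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns subject_id, sex, level and height columns")
  if (!all(cohort$level %in% 1:17)) stop("levels must be in 1..17")
  invisible(cohort)
}

#' Sex-stratified mean heights and deltas per vertebral level
#'
#' Per-level male and female mean heights with the absolute difference
#' (male - female, rounded to 2 decimals) and the relative difference
#' (percent of the male mean, rounded to 1 decimal). Levels missing one sex
#' are omitted and flagged in the \code{"missing"} attribute.
#'
#' @param cohort height records (columns \code{subject_id}, \code{sex},
#'   \code{level}, and the height columns).
#' @param heightType which height column to summarize ("Ha", "Hp" or "Hc").
#' @return data.frame with columns \code{level}, \code{label},
#'   \code{male_mean}, \code{female_mean}, \code{delta_mm},
#'   \code{delta_pct}.
#' @export
sexDeltaTable <- function(cohort, heightType = "Hp") {
  .checkCohort(cohort)
  h <- cohort[[heightType]]
  rows <- lapply(sort(unique(cohort$level)), function(l) {
    sel <- cohort$level == l
    mM <- mean(h[sel & cohort$sex == "male"])
    mF <- mean(h[sel & cohort$sex == "female"])
    if (!is.finite(mM) || !is.finite(mF)) return(NULL)
    data.frame(level = l, label = levelLabels()[l],
               male_mean = mM, female_mean = mF,
               delta_mm = round(mM - mF, 2),
               delta_pct = round(100 * (mM - mF) / mM, 1))
  })
  missing <- setdiff(sort(unique(cohort$level)),
                     vapply(Filter(Negate(is.null), rows), `[[`, 1, "level"))
  out <- do.call(rbind, rows)
  attr(out, "missing") <- missing
  out
}

#' Anterior wedge and biconcavity indices
#'
#' Per-record wedge (\code{Ha/Hp}) and biconcavity (\code{Hc/Hp}) indices,
#' plus sex-level means per level computed as the mean over subjects of the
#' per-subject ratios (not the ratio of means).
#'
#' @param cohort height records with \code{Ha}, \code{Hp}, \code{Hc}.
#' @return list with \code{records} (per-record indices) and \code{means}
#'   (per level x sex mean indices).
#' @export
wedgeBiconcavity <- function(cohort) {
  .checkCohort(cohort)
  if (any(cohort$Hp <= 0)) stop("invalid-record error: Hp must be positive")
  rec <- data.frame(subject_id = cohort$subject_id, sex = cohort$sex,
                    level = cohort$level,
                    wedge = cohort$Ha / cohort$Hp,
                    biconcavity = cohort$Hc / cohort$Hp)
  means <- aggregate(cbind(wedge, biconcavity) ~ level + sex, data = rec, mean)
  means <- means[order(means$sex, means$level), ]
  rownames(means) <- NULL
  list(records = rec, means = means)
}

#' Per-level two-sample t-tests for sex differences
#'
#' Pooled-variance (Student) two-sample t-test of male vs female heights at
#' each level, two-sided; Welch's correction available via \code{welch}.
#' Levels with fewer than 2 subjects in either sex are skipped and flagged.
#'
#' @param cohort height records.
#' @param heightType height column to test.
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return data.frame with columns \code{level}, \code{label}, \code{t},
#'   \code{p}, \code{flag}.
#' @export
perLevelTest <- function(cohort, heightType = "Hp", welch = FALSE) {
  .checkCohort(cohort)
  h <- cohort[[heightType]]
  do.call(rbind, lapply(sort(unique(cohort$level)), function(l) {
    xm <- h[cohort$level == l & cohort$sex == "male"]
    xf <- h[cohort$level == l & cohort$sex == "female"]
    if (length(xm) < 2 || length(xf) < 2)
      return(data.frame(level = l, label = levelLabels()[l],
                        t = NA_real_, p = NA_real_, flag = "insufficient"))
    tt <- stats::t.test(xm, xf, var.equal = !welch)
    data.frame(level = l, label = levelLabels()[l],
               t = unname(tt$statistic), p = tt$p.value, flag = "ok")
  }))
}

#' Power of the two-sided two-sample t-test
#'
#' Exact power via the noncentral t distribution with noncentrality
#' \code{d * sqrt(n1 * n2 / (n1 + n2))} and \code{n1 + n2 - 2} degrees of
#' freedom.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d Cohen's d effect size.
#' @param alpha two-sided significance level in (0, 1).
#' @return power in [0, 1].
#' @export
#' @examples
#' powerTwoSample(129, 133, d = 0.4)
powerTwoSample <- function(n1, n2, d, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Intraclass correlation of the average of k raters from the mean squares
#' of the two-way ANOVA decomposition (subjects x raters, no replication):
#' \code{ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)}, where MSR, MSC and
#' MSE are the subject, rater and residual mean squares.
#'
#' @param ratings numeric n x k matrix (subjects in rows, raters in
#'   columns), no missing cells, n >= 5, k >= 2.
#' @return the ICC value.
#' @export
icc2k <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5 || k < 2) stop("need >= 5 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must have no missing cells")
  g <- mean(ratings)
  sst <- sum((ratings - g)^2)
  if (sst == 0) stop("undefined-ICC error: zero total variance")
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  msr <- k * sum((rowM - g)^2) / (n - 1)
  msc <- n * sum((colM - g)^2) / (k - 1)
  mse <- (sst - k * sum((rowM - g)^2) - n * sum((colM - g)^2)) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

#' Mean slope of a height curve over a level segment
#'
#' \code{slope_mm} is the mean of consecutive first differences within the
#' segment; \code{slope_pct} is the mean of the consecutive percent changes
#' (each difference divided by the more cranial level's mean, times 100).
#'
#' @param meanCurve numeric vector of per-level means indexed 1..17 (or a
#'   named vector covering the segment).
#' @param segment integer range of levels, e.g. \code{9:13} for T9--L1.
#' @return named numeric: \code{slope_mm}, \code{slope_pct}.
#' @export
segmentMeanSlope <- function(meanCurve, segment) {
  if (length(segment) < 2) stop("segment must span at least 2 levels")
  if (min(segment) < 1 || max(segment) > length(meanCurve))
    stop("segment out of range of the mean curve")
  x <- meanCurve[segment]
  d <- diff(x)
  c(slope_mm = mean(d), slope_pct = mean(100 * d / x[-length(x)]))
}

#' Exclusion bookkeeping for an extraction run
#'
#' Reconciles the vertebra counts of a cohort: analyzed = total - excluded,
#' the exclusion percentage, and the number of height measurements
#' (3 per analyzed vertebra).
#'
#' @param total total vertebra count entering the pipeline.
#' @param excluded integer vector of per-reason exclusion counts.
#' @return named numeric: \code{total}, \code{excluded}, \code{analyzed},
#'   \code{excluded_pct} (2 dp), \code{measurements}.
#' @export
#' @examples
#' exclusionTally(3117, c(missegmented = 77, partial = 115))
exclusionTally <- function(total, excluded = integer()) {
  ex <- sum(excluded)
  if (total < 0 || ex < 0 || ex > total)
    stop("counts must be non-negative and excluded <= total")
  analyzed <- total - ex
  c(total = total, excluded = ex, analyzed = analyzed,
    excluded_pct = round(100 * ex / total, 2),
    measurements = 3 * analyzed)
}
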