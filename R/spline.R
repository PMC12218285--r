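# Mixed-effects truncated-power spline regression of vertebral height on
# vertebral level (T1..L5 coded 1..17), with sex indicator and per-subject
# random intercept and slope.

#' Build the truncated-power spline design
#'
#' Cubic basis: \code{ver}, \code{ver^2}, \code{ver^3} plus one truncated
#' term \code{(ver - k)^3_+} per knot (zero at and below the knot), giving a
#' cubic spline with continuous first and second derivatives at the knots.
#' Linear basis: \code{ver} plus \code{(ver - k)_+} per knot (continuous
#' piecewise-linear).
#'
#' @param levels integer vertebral levels in 1..17.
#' @param sex optional character vector ("male"/"female"); adds a 0/1
#'   \code{male} column.
#' @param knots interior knots, strictly inside 1..17 (may be empty).
#' @param basis "cubic" or "linear".
#' @return data.frame of basis columns (no intercept column).
#' @export
#' @examples
#' buildSplineDesign(c(1, 13, 17), knots = c(9, 13))
buildSplineDesign <- function(levels, sex = NULL, knots = c(9, 13),
                              basis = c("cubic", "linear")) {
  basis <- match.arg(basis)
  if (any(levels < 1 | levels > 17)) stop("levels must be in 1..17")
  if (length(knots) && any(knots <= 1 | knots >= 17))
    stop("knots must lie strictly inside 1..17")
  ver <- as.numeric(levels)
  out <- if (basis == "cubic") {
    d <- data.frame(ver = ver, ver2 = ver^2, ver3 = ver^3)
    for (k in knots) d[[paste0("tp", k)]] <- pmax(ver - k, 0)^3
    d
  } else {
    d <- data.frame(ver = ver)
    for (k in knots) d[[paste0("lin", k)]] <- pmax(ver - k, 0)
    d
  }
  if (!is.null(sex)) out$male <- as.numeric(sex == "male")
  out
}

# Shared fitting engine behind fitMixedSpline / fitLinearSpline.
.fitSpline <- function(cohort, heightType, knots, basis, randomEffects,
                       includeSex, REML) {
  .checkCohort(cohort)
  y <- cohort[[heightType]]
  if (is.null(y)) stop("unknown height type: ", heightType)
  if (includeSex && length(unique(cohort$sex)) < 2)
    includeSex <- FALSE
  X <- buildSplineDesign(cohort$level, if (includeSex) cohort$sex,
                         knots = knots, basis = basis)
  d <- cbind(y = y, X, subject = factor(cohort$subject_id))
  fixedTerms <- names(X)
  Xm <- cbind(1, as.matrix(X))
  if (qr(Xm)$rank < ncol(Xm))
    stop("rank error: singular design (too few distinct levels for the basis)")
  fixedF <- paste("y ~", paste(fixedTerms, collapse = " + "))

  if (randomEffects == "none") {
    fit <- stats::lm(stats::as.formula(fixedF), data = d)
    beta <- stats::coef(fit)
    # a perfect (interpolating) fit makes vcov warn; the SEs are then 0
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    ll <- stats::logLik(fit)
    varF <- stats::var(drop(Xm %*% beta))
    varR <- 0
    sig <- sqrt(sum(stats::residuals(fit)^2) / stats::nobs(fit))  # ML sigma
    ranSD <- c(sdIntercept = NA_real_, sdSlope = NA_real_, corr = NA_real_)
  } else {
    nSub <- length(unique(d$subject))
    if (nSub < 8) stop("need >= 8 subjects for the mixed model")
    if (min(table(d$subject)) < 2)
      stop("need >= 2 observations per subject")
    reTerm <- if (randomEffects == "correlated") "(1 + ver | subject)"
              else "(1 | subject) + (0 + ver | subject)"
    ctrl <- lme4::lmerControl(calc.derivs = FALSE, check.scaleX = "ignore")
    form <- stats::as.formula(paste(fixedF, "+", reTerm))
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(form, data = d, REML = REML, control = ctrl),
               error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
    if (inherits(fit, "error") && randomEffects == "correlated") {
      # fall back to independent random effects
      return(.fitSpline(cohort, heightType, knots, basis, "independent",
                        includeSex, REML))
    }
    if (inherits(fit, "error"))
      stop("convergence error: ", conditionMessage(fit))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    ll <- stats::logLik(fit)
    vc <- lme4::VarCorr(fit)
    tau <- matrix(0, 2, 2)
    for (g in vc) {
      nms <- rownames(g)
      if ("(Intercept)" %in% nms) {
        tau[1, 1] <- tau[1, 1] + g["(Intercept)", "(Intercept)"]
        if ("ver" %in% nms) {
          tau[2, 2] <- tau[2, 2] + g["ver", "ver"]
          tau[1, 2] <- tau[2, 1] <- g["(Intercept)", "ver"]
        }
      } else if ("ver" %in% nms) tau[2, 2] <- tau[2, 2] + g["ver", "ver"]
    }
    varF <- stats::var(drop(Xm %*% beta))
    ver <- d$ver
    varR <- mean(tau[1, 1] + 2 * tau[1, 2] * ver + tau[2, 2] * ver^2)
    sig <- stats::sigma(fit)
    ranSD <- c(sdIntercept = sqrt(tau[1, 1]), sdSlope = sqrt(tau[2, 2]),
               corr = if (tau[1, 1] > 0 && tau[2, 2] > 0)
                 tau[1, 2] / sqrt(tau[1, 1] * tau[2, 2]) else NA_real_)
  }

  p <- attr(ll, "df")
  nObs <- length(y)
  varE <- sig^2
  tot <- varF + varR + varE
  new("MixedFit",
      heightType = heightType, basis = basis, knots = as.numeric(knots),
      coefficients = beta, seFixed = se, ranefSD = ranSD, sigma = sig,
      varFixed = varF, varRandom = varR, varResidual = varE,
      logLik = as.numeric(ll), df = p,
      AIC = -2 * as.numeric(ll) + 2 * p,
      BIC = -2 * as.numeric(ll) + p * log(nObs),
      nObs = nObs, nSubjects = length(unique(cohort$subject_id)),
      R2marginal = varF / tot, R2conditional = (varF + varR) / tot,
      randomEffects = randomEffects,
      dataSignature = c(nObs, sum(y), sum(y^2)),
      model = fit)
}

#' Fit the cubic truncated-power spline mixed model
#'
#' Maximum-likelihood fit of vertebral height on the cubic spline basis with
#' knots on the level axis (default 9 and 13, i.e. T9 and L1), a male
#' indicator, and per-subject random intercept and slope in \code{ver}
#' (correlated by default; falls back to independent effects if the
#' correlated fit fails). ML (not REML) is the default so that AIC/BIC are
#' comparable across fixed-effect structures.
#'
#' @param cohort height records.
#' @param heightType height column to model.
#' @param knots interior knots.
#' @param randomEffects "correlated", "independent", or "none" (plain
#'   least-squares fit of the same fixed effects).
#' @param includeSex include the male indicator (pooled-sex model); set
#'   FALSE (or pass a single-sex cohort) for sex-stratified fits.
#' @param REML use REML instead of ML (variance reporting only; do not
#'   compare REML fits with different fixed effects).
#' @return a \linkS4class{MixedFit}.
#' @export
fitMixedSpline <- function(cohort, heightType = "Hp", knots = c(9, 13),
                           randomEffects = c("correlated", "independent", "none"),
                           includeSex = TRUE, REML = FALSE) {
  .fitSpline(cohort, heightType, knots, "cubic", match.arg(randomEffects),
             includeSex, REML)
}

#' Fit the piecewise-linear spline comparator
#'
#' Same random-effects structure and outputs as
#' \code{\link{fitMixedSpline}}, but with a continuous piecewise-linear mean
#' over the segments delimited by the knots (default T1-T9, T10-L1, L2-L5).
#'
#' @inheritParams fitMixedSpline
#' @return a \linkS4class{MixedFit}.
#' @export
fitLinearSpline <- function(cohort, heightType = "Hp", knots = c(9, 13),
                            randomEffects = c("correlated", "independent", "none"),
                            includeSex = TRUE, REML = FALSE) {
  .fitSpline(cohort, heightType, knots, "linear", match.arg(randomEffects),
             includeSex, REML)
}

#' Compare fitted models by information criteria
#'
#' Tabulates \code{AIC = -2 logLik + 2 p} and
#' \code{BIC = -2 logLik + p log(n)} for models fitted on identical data
#' (verified via an internal data checksum) and ranks them by AIC.
#'
#' @param fits named list of \linkS4class{MixedFit} objects.
#' @return data.frame with columns \code{model}, \code{df}, \code{logLik},
#'   \code{AIC}, \code{BIC}, \code{rank}.
#' @export
compareModels <- function(fits) {
  stopifnot(length(fits) >= 1)
  sig <- lapply(fits, function(f) f@dataSignature)
  if (!all(vapply(sig, function(s) isTRUE(all.equal(s, sig[[1]])), TRUE)))
    stop("comparison error: models were not fitted on identical data")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  out <- data.frame(
    model = nm,
    df = vapply(fits, function(f) f@df, 1),
    logLik = vapply(fits, function(f) f@logLik, 1),
    AIC = vapply(fits, function(f) f@AIC, 1),
    BIC = vapply(fits, function(f) f@BIC, 1))
  out$rank <- rank(out$AIC, ties.method = "min")
  rownames(out) <- NULL
  out
}

#' Search candidate knot sets by AIC
#'
#' Fits the mixed spline for every candidate knot set and returns the
#' AIC-minimizing set together with the full criterion table.
#'
#' @param cohort height records.
#' @param candidates list of numeric knot vectors (an empty vector means a
#'   knot-free cubic polynomial).
#' @param heightType height column to model.
#' @param basis "cubic" or "linear".
#' @param ... passed to the fitting function.
#' @return list with \code{best} (the winning knot vector) and \code{table}
#'   (data.frame of knots, df, logLik, AIC, BIC).
#' @export
knotSearch <- function(cohort, candidates = list(c(9, 13)),
                       heightType = "Hp", basis = c("cubic", "linear"), ...) {
  basis <- match.arg(basis)
  if (!length(candidates)) stop("need at least one candidate knot set")
  fitFun <- if (basis == "cubic") fitMixedSpline else fitLinearSpline
  fits <- lapply(candidates, function(k)
    fitFun(cohort, heightType = heightType, knots = k, ...))
  lab <- vapply(candidates, function(k)
    if (length(k)) paste(k, collapse = ",") else "none", "")
  tab <- data.frame(
    knots = lab,
    df = vapply(fits, function(f) f@df, 1),
    logLik = vapply(fits, function(f) f@logLik, 1),
    AIC = vapply(fits, function(f) f@AIC, 1),
    BIC = vapply(fits, function(f) f@BIC, 1))
  best <- which.min(tab$AIC)
  list(best = candidates[[best]], table = tab)
}
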