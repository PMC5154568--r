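## The study's statistical layer: derived ocular hemodynamics, test-retest
## repeatability (COV and ANOVA-based ICC), Pearson/linear-regression
## associations, paired and independent comparisons, and the scan
## success-rate chi-square.

#' Derived ocular hemodynamics: MAP, PPA and OPP
#'
#' From systolic/diastolic blood pressure and intraocular pressure:
#' mean arterial pressure \code{MAP = DBP + (SBP - DBP) / 3}, pulse
#' pressure amplitude \code{PPA = SBP - DBP}, and ocular perfusion pressure
#' (seated) \code{OPP = 2/3 MAP - IOP}. These identities are exact, not
#' fitted. The alternative reading \code{mapFormula = "printed"} uses
#' \code{MAP = SBP + (SBP - DBP) / 3} for fidelity experiments; the default
#' is the standard formula, which is the one consistent with typical
#' published summary tables.
#'
#' @param sbp systolic blood pressure, mmHg (vectorized).
#' @param dbp diastolic blood pressure, mmHg; must satisfy sbp > dbp > 0.
#' @param iop intraocular pressure, mmHg (>= 0).
#' @param mapFormula \code{"standard"} (default) or \code{"printed"}.
#' @return A data.frame with columns \code{sbp, dbp, iop, map, ppa, opp}.
#' @examples
#' derivedHemodynamics(128, 81, 12.8)  # PPA 47, MAP ~96, OPP ~51
#' @export
derivedHemodynamics <- function(sbp, dbp, iop,
                                mapFormula = c("standard", "printed")) {
  mapFormula <- match.arg(mapFormula)
  if (any(!(sbp > dbp))) stop("need sbp > dbp")
  if (any(dbp <= 0)) stop("need dbp > 0")
  if (any(iop < 0)) stop("need iop >= 0")
  map <- switch(mapFormula,
                standard = dbp + (sbp - dbp) / 3,
                printed = sbp + (sbp - dbp) / 3)
  data.frame(sbp = sbp, dbp = dbp, iop = iop, map = map,
             ppa = sbp - dbp, opp = 2 / 3 * map - iop)
}

## Coerce a subjects x repeats input, dropping rows with missing values.
.repeatMatrix <- function(measurements) {
  m <- as.matrix(measurements)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 subjects with complete repeats")
  if (ncol(m) < 2) stop("need at least 2 repeats")
  m
}

#' Coefficient of variation of repeated measurements
#'
#' Test-retest COV: the mean over subjects of the within-subject standard
#' deviation of the repeats (n - 1 denominator), divided by the grand mean,
#' in percent. Scale-invariant; zero iff every subject's repeats are
#' identical.
#'
#' @param measurements numeric matrix or data.frame, subjects in rows,
#'   repeats in columns; rows with missing values are dropped.
#' @return COV in percent.
#' @examples
#' coefficientOfVariation(rbind(c(9, 11), c(19, 21)))  # 100 * sqrt(2) / 15
#' @export
coefficientOfVariation <- function(measurements) {
  m <- .repeatMatrix(measurements)
  g <- mean(m)
  if (g <= 0) stop("coefficient of variation undefined: grand mean <= 0")
  100 * mean(apply(m, 1, stats::sd)) / g
}

#' Intraclass correlation coefficient from repeated-measures ANOVA
#'
#' Test-retest ICC of a complete subjects x repeats matrix, computed from
#' the mean squares of the repeated-measures ANOVA. The default form is the
#' two-way mixed-effects, consistency, single-measurement ICC(3,1) =
#' (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error); the
#' two-way random absolute-agreement ICC(2,1) and the one-way form are
#' available via \code{form}. When the error mean square is exactly zero
#' and subjects differ, the ICC is 1 by the limit of the formula.
#'
#' @param measurements numeric matrix or data.frame, subjects x repeats;
#'   rows with missing values are dropped first.
#' @param form \code{"icc3"} (default), \code{"icc2"} or \code{"oneway"}.
#' @return A list with \code{icc}, \code{form}, \code{nSubjects},
#'   \code{nRepeats}, and the ANOVA mean squares \code{msSubjects},
#'   \code{msRepeats}, \code{msError}.
#' @examples
#' intraclassCorrelation(rbind(c(1, 2), c(3, 4), c(5, 6)))
#' @export
intraclassCorrelation <- function(measurements,
                                  form = c("icc3", "icc2", "oneway")) {
  form <- match.arg(form)
  m <- .repeatMatrix(measurements)
  n <- nrow(m); k <- ncol(m)
  # perfectly repeated measurements: ICC is 1 in the limit, even when the
  # subjects coincide (where the ANOVA ratio would be 0/0)
  wss <- sum((m - rowMeans(m))^2)
  if (wss <= 1e-12 * max(sum((m - mean(m))^2), 1))
    return(list(icc = 1, form = form, nSubjects = n, nRepeats = k,
                msSubjects = sum((rowMeans(m) - mean(m))^2) * k / (n - 1),
                msRepeats = 0, msError = 0))
  long <- data.frame(value = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(value ~ subject + rater, data = long)
  ms <- summary(fit)[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  msw <- (msc * (k - 1) + mse * (n - 1) * (k - 1)) / (n * (k - 1))
  icc <- switch(form,
    icc3 = {
      den <- msr + (k - 1) * mse
      if (den == 0) NA_real_ else (msr - mse) / den
    },
    icc2 = {
      den <- msr + (k - 1) * mse + k * (msc - mse) / n
      if (den == 0) NA_real_ else (msr - mse) / den
    },
    oneway = {
      den <- msr + (k - 1) * msw
      if (den == 0) NA_real_ else (msr - msw) / den
    })
  list(icc = unname(icc), form = form, nSubjects = n, nRepeats = k,
       msSubjects = unname(msr), msRepeats = unname(msc),
       msError = unname(mse))
}

#' Pearson correlation and linear regression of an index on a covariate
#'
#' Pearson r with the two-sided t-test on n - 2 degrees of freedom, the
#' least-squares line, and the pointwise 95 percent confidence band of the
#' mean response (the dashed band of a standard regression scatter plot).
#'
#' @param x covariate values (e.g. age or PPA).
#' @param y index values.
#' @param level confidence level of the band (default 0.95).
#' @return A list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n}, \code{df}, and \code{band}, a function of new covariate
#'   values returning a data.frame \code{fit, lwr, upr}.
#' @examples
#' a <- associationTest(1:20, 2 * (1:20) + rnorm(20))
#' a$band(c(5, 15))
#' @export
associationTest <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete (x, y) pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("association undefined: zero variance in x or y")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  band <- function(xnew) {
    pr <- stats::predict(fit, newdata = data.frame(x = xnew),
                         interval = "confidence", level = level)
    as.data.frame(pr)
  }
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x), df = length(x) - 2, band = band)
}

#' Paired comparison of an index before and after a condition change
#'
#' Two-sided paired t-test. When the paired differences have zero variance
#' the test statistic degenerates: p = 1 if the common difference is zero
#' and p = 0 otherwise (the limits of the t-test).
#'
#' @param before,after paired measurements of equal length (n >= 2); pairs
#'   with missing values are dropped.
#' @return A list with \code{t}, \code{df}, \code{p}, \code{meanBefore},
#'   \code{meanAfter}, \code{meanDiff} (after - before), \code{n}.
#' @export
pairedComparison <- function(before, after) {
  if (length(before) != length(after))
    stop("paired comparison needs equal-length vectors")
  ok <- stats::complete.cases(before, after)
  before <- before[ok]; after <- after[ok]
  if (length(before) < 2) stop("need at least 2 complete pairs")
  d <- after - before
  eps <- 1e-10 * max(1, abs(mean(d)))
  if (stats::sd(d) <= eps) {
    p <- if (abs(mean(d)) <= eps) 1 else 0
    tstat <- if (abs(mean(d)) <= eps) 0 else sign(mean(d)) * Inf
  } else {
    tt <- stats::t.test(after, before, paired = TRUE)
    p <- tt$p.value
    tstat <- unname(tt$statistic)
  }
  list(t = tstat, df = length(d) - 1, p = p,
       meanBefore = mean(before), meanAfter = mean(after),
       meanDiff = mean(d), n = length(d))
}

#' Independent two-group comparison
#'
#' Two-sided independent-samples t-test, pooled variance by default (Welch
#' via \code{varEqual = FALSE}). Degenerate zero-variance groups follow the
#' t-test limits: p = 1 for equal constant groups, p = 0 otherwise.
#'
#' @param groupA,groupB numeric vectors (each n >= 2 after dropping NAs).
#' @param varEqual pooled variance if TRUE (default).
#' @return A list with \code{t}, \code{df}, \code{p}, \code{meanA},
#'   \code{meanB}, \code{meanDiff} (A - B).
#' @export
groupComparison <- function(groupA, groupB, varEqual = TRUE) {
  groupA <- groupA[!is.na(groupA)]
  groupB <- groupB[!is.na(groupB)]
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  epsAB <- 1e-10 * max(1, abs(mean(groupA)), abs(mean(groupB)))
  if (stats::sd(groupA) <= epsAB && stats::sd(groupB) <= epsAB) {
    eq <- abs(mean(groupA) - mean(groupB)) <= epsAB
    return(list(t = if (eq) 0 else sign(mean(groupA) - mean(groupB)) * Inf,
                df = length(groupA) + length(groupB) - 2,
                p = if (eq) 1 else 0, meanA = mean(groupA),
                meanB = mean(groupB), meanDiff = mean(groupA) - mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = varEqual)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       meanA = mean(groupA), meanB = mean(groupB),
       meanDiff = mean(groupA) - mean(groupB))
}

#' Chi-square comparison of two scan success rates
#'
#' Pearson chi-square on the 2 x 2 success/failure table, one degree of
#' freedom, two-sided, without continuity correction by default (Yates'
#' correction via \code{correct = TRUE}). Also returns both success rates
#' as percentages rounded to one decimal. If any expected cell count falls
#' below 1 a warning is attached but the result is still returned.
#'
#' @param successA,totalA successes and total scans of group A.
#' @param successB,totalB successes and total scans of group B.
#' @param correct apply Yates' continuity correction (default FALSE).
#' @return A list with \code{chisq}, \code{df}, \code{p}, \code{rateA},
#'   \code{rateB} (percent, one decimal).
#' @examples
#' successRateTest(225, 240, 237, 240)  # rates 93.8 / 98.8, p ~ 0.004
#' @export
successRateTest <- function(successA, totalA, successB, totalB,
                            correct = FALSE) {
  if (any(c(totalA, totalB) <= 0)) stop("totals must be > 0")
  if (successA > totalA || successB > totalB)
    stop("successes cannot exceed totals")
  tab <- rbind(c(successA, totalA - successA),
               c(successB, totalB - successB))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count below 1: chi-square approximation is poor")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       rateA = round(100 * successA / totalA, 1),
       rateB = round(100 * successB / totalB, 1))
}
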