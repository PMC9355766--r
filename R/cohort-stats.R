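# Statistical layer: per-specimen aggregation, metric-versus-age
# regressions, relative-change statements and the sex comparison.

#' Aggregate region metrics into per-specimen summaries
#'
#' Unweighted mean and standard deviation of each numeric metric across
#' the imaged regions of one specimen (the regression units are specimens,
#' not regions). With a single region the sd is reported as 0 and flagged.
#'
#' @param regionMetrics data.frame of per-region metric values (numeric
#'   columns are aggregated, others ignored).
#' @return list with \code{mean} and \code{sd} (named numeric),
#'   \code{nRegions}, and \code{sdDefined} (FALSE when only one region).
#' @examples
#' aggregateSpecimen(data.frame(width_um = c(4, 5, 6)))
#' @export
aggregateSpecimen <- function(regionMetrics) {
  if (!is.data.frame(regionMetrics) || nrow(regionMetrics) == 0L)
    stop("'regionMetrics' must be a non-empty data.frame")
  num <- vapply(regionMetrics, is.numeric, logical(1))
  if (!any(num)) stop("no numeric metric columns to aggregate")
  m <- vapply(regionMetrics[num], mean, numeric(1))
  n <- nrow(regionMetrics)
  s <- if (n > 1) vapply(regionMetrics[num], stats::sd, numeric(1))
       else stats::setNames(rep(0, sum(num)), names(regionMetrics)[num])
  list(mean = m, sd = s, nRegions = n, sdDefined = n > 1)
}

#' Fit a metric-versus-age linear regression
#'
#' Ordinary least squares of the per-specimen metric on age, with the
#' Pearson correlation and its two-sided t-test p-value.
#'
#' @param ages ages in years (one per specimen).
#' @param values metric values, same length, n >= 3.
#' @param metricName label stored on the result.
#' @return an \linkS4class{AgeRegression}.
#' @examples
#' fitAgeRegression(c(20, 40, 60, 80), c(4.1, 4.7, 5.3, 5.9), "width_um")
#' @export
fitAgeRegression <- function(ages, values, metricName = "metric") {
  if (length(ages) != length(values))
    stop("'ages' and 'values' must have the same length")
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 3L)
    stop("at least 3 specimens are required for a regression")
  if (stats::sd(ages) == 0) stop("ages are constant; slope undefined")
  if (stats::sd(values) == 0)
    stop("metric values are constant; Pearson correlation undefined")
  fit <- stats::lm(values ~ ages)
  ct <- suppressWarnings(stats::cor.test(ages, values, method = "pearson"))
  new("AgeRegression", metricName = metricName,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      pearsonR = unname(ct$estimate), pValue = ct$p.value,
      n = length(ages), residualSd = stats::sigma(fit))
}

#' Relative change of a regressed metric between two ages
#'
#' Evaluates the fitted line at two ages and reports the percent change in
#' magnitude, \code{100 (|line(to)| - |line(from)|) / |line(from)|} -- the
#' natural reading of "X percent larger" for a negative-valued index. The
#' signed change \code{100 (line(to) - line(from)) / line(from)} is
#' reported alongside; if the line crosses zero between the two ages the
#' result is flagged.
#'
#' @param reg an \linkS4class{AgeRegression}, or \code{c(slope, intercept)}.
#' @param ageFrom,ageTo ages in years.
#' @return list with \code{percentMagnitude}, \code{percentSigned},
#'   \code{valueFrom}, \code{valueTo}, \code{crossesZero}.
#' @examples
#' relativeChange(c(-0.003, -0.25), 20, 80)$percentMagnitude  # 58.06
#' @export
relativeChange <- function(reg, ageFrom, ageTo) {
  co <- if (is(reg, "AgeRegression")) c(reg@slope, reg@intercept)
        else as.numeric(reg)
  if (length(co) != 2L || any(!is.finite(co)))
    stop("'reg' must be an AgeRegression or c(slope, intercept)")
  vFrom <- co[1] * ageFrom + co[2]
  vTo <- co[1] * ageTo + co[2]
  if (vFrom == 0)
    stop("the line is zero at 'ageFrom'; relative change undefined")
  crosses <- sign(vFrom) != sign(vTo) && vTo != 0
  list(
    percentMagnitude = 100 * (abs(vTo) - abs(vFrom)) / abs(vFrom),
    percentSigned = 100 * (vTo - vFrom) / vFrom,
    valueFrom = vFrom, valueTo = vTo, crossesZero = crosses)
}

#' Mann-Whitney U comparison between two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test, exact for small
#' samples without ties, normal approximation with mid-ranks otherwise
#' (no continuity correction, so identical groups give p = 1).
#'
#' @param x,y the two groups (e.g. ages of male and female specimens).
#' @return list with \code{U}, \code{p}, \code{method}, \code{nx},
#'   \code{ny}.
#' @examples
#' sexComparison(c(19, 27, 44, 60), c(24, 35, 50, 71, 82))
#' @export
sexComparison <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = !ties, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (!ties && length(x) < 50 && length(y) < 50) "exact"
                else "normal approximation (mid-ranks)",
       nx = length(x), ny = length(y))
}
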