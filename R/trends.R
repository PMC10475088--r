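#' Ordinary least squares trend of an annual series
#'
#' Fits `value ~ year` by least squares and reports the slope, its 95%
#' confidence interval (slope standard error times the t quantile with
#' n-2 degrees of freedom) and the two-tailed t-test p-value for a zero
#' slope.  For these fits `p < 0.05` holds exactly when the confidence
#' interval excludes zero.  A zero-residual (perfect) fit returns p-value
#' 0 and a zero-width interval with a warning, the t statistic being
#' undefined there.
#'
#' @param year numeric vector of years (>= 3 distinct values), or a
#'   data.frame with columns `year` and `value`.
#' @param value numeric vector of annual values.
#' @param alpha significance level for the confidence interval
#'   (default 0.05, i.e. a 95% interval).
#' @return data.frame with one row: slope, intercept, ci95_low,
#'   ci95_high, p_value, n_years, method.
#' @examples
#' olsTrend(2001:2010, 0.5 * (2001:2010) + rnorm(10, sd = 0.1))
#' @export
olsTrend <- function(year, value = NULL, alpha = 0.05) {
  if (is.data.frame(year)) { value <- year$value; year <- year$year }
  keep <- is.finite(year) & is.finite(value)
  year <- year[keep]; value <- value[keep]
  if (length(unique(year)) < 3L)
    stop("need at least 3 distinct years for a trend", call. = FALSE)
  fit <- lm(value ~ year)
  # summary.lm warns about zero-residual fits; the dedicated warning below
  # reports that case with the convention used here
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["year", "Estimate"]
  se <- sm["year", "Std. Error"]
  df <- fit$df.residual
  resVar <- sum(fit$residuals^2) / max(df, 1)
  if (resVar < 1e-24 * max(mean(value^2), 1)) {
    warning("zero-residual fit: confidence interval collapsed to the slope",
            call. = FALSE)
    ciLow <- ciHigh <- slope
    p <- 0
  } else {
    tq <- qt(1 - alpha / 2, df)
    ciLow <- slope - tq * se
    ciHigh <- slope + tq * se
    p <- 2 * pt(-abs(slope / se), df)
  }
  data.frame(slope = slope, intercept = sm["(Intercept)", "Estimate"],
             ci95_low = ciLow, ci95_high = ciHigh, p_value = p,
             n_years = length(year), method = "ols")
}

#' Mann-Kendall trend with Sen's slope
#'
#' Non-parametric trend test: the Mann-Kendall S statistic with the
#' standard tie-corrected variance and a normal approximation (continuity
#' corrected) for the two-tailed p-value; the slope reported is Sen's
#' estimator, the median of all pairwise slopes.
#'
#' @inheritParams olsTrend
#' @return data.frame with one row: slope (Sen), intercept, ci95_low,
#'   ci95_high (`NA`: no interval is constructed for this method),
#'   p_value, n_years, method, and an `S` column with the Mann-Kendall
#'   statistic.
#' @export
mannKendallTrend <- function(year, value = NULL) {
  if (is.data.frame(year)) { value <- year$value; year <- year$year }
  keep <- is.finite(year) & is.finite(value)
  year <- year[keep]; value <- value[keep]
  n <- length(value)
  if (n < 4L)
    stop("need at least 4 points for the Mann-Kendall test", call. = FALSE)
  ord <- order(year)
  year <- year[ord]; value <- value[ord]
  pairs <- combn(n, 2)
  dy <- value[pairs[2, ]] - value[pairs[1, ]]
  dx <- year[pairs[2, ]] - year[pairs[1, ]]
  S <- sum(sign(dy))
  # tie correction on the values
  ties <- table(value)
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS) else 0
  p <- 2 * pnorm(-abs(z))
  slopes <- dy[dx != 0] / dx[dx != 0]
  sen <- median(slopes)
  data.frame(slope = sen, intercept = median(value - sen * year),
             ci95_low = NA_real_, ci95_high = NA_real_, p_value = p,
             n_years = n, method = "mann_kendall", S = S)
}

#' Agreement between OLS and Sen slope estimates
#'
#' Fits both estimators to each series of a collection and returns the
#' coefficient of determination (squared Pearson correlation) between the
#' two slope vectors — the standard cross-check that parametric trends
#' are not artefacts of the linear model.
#'
#' @param seriesList list of data.frames, each with columns `year` and
#'   `value` (>= 3 series).
#' @return list with `r2`, and the `ols` and `sen` slope vectors.
#' @export
trendConsistency <- function(seriesList) {
  if (length(seriesList) < 3L)
    stop("need at least 3 series to assess slope agreement", call. = FALSE)
  if (length(seriesList) < 5L)
    message("trendConsistency: few series; R^2 is unstable at low n")
  ols <- vapply(seriesList, function(s) olsTrend(s)$slope, numeric(1))
  sen <- vapply(seriesList, function(s) mannKendallTrend(s)$slope,
                numeric(1))
  if (sd(ols) == 0 || sd(sen) == 0)
    stop("degenerate slope vectors: zero variance", call. = FALSE)
  list(r2 = cor(ols, sen)^2, ols = ols, sen = sen)
}

#' Period trend table for an exposure series
#'
#' Fits [olsTrend()] (and optionally [mannKendallTrend()]) to the `E` and
#' `NE` series of every scope over configurable sub-periods.  The default
#' periods split the series at the pivot year with the pivot included in
#' both, mirroring a growth period and a decline period.
#'
#' @param series an [exposureSeries()] data.frame.
#' @param periods list of `c(first, last)` year pairs.
#' @param what column to fit, `"E"` (default) or `"NE"`.
#' @param methods subset of `c("ols", "mann_kendall")`.
#' @return data.frame with scope, scope_type, period, and the trend
#'   columns.
#' @export
trendTable <- function(series, periods = list(c(1998, 2011), c(2011, 2019)),
                       what = "E", methods = "ols") {
  scopes <- unique(series[, c("scope", "scope_type")])
  rows <- list()
  for (i in seq_len(nrow(scopes))) {
    sc <- scopes$scope[i]
    sub <- series[series$scope == sc & is.finite(series[[what]]), ]
    for (per in periods) {
      ss <- sub[sub$year >= per[1] & sub$year <= per[2], ]
      if (nrow(ss) < 3L) next
      for (m in methods) {
        tr <- if (m == "ols") olsTrend(ss$year, ss[[what]])
              else mannKendallTrend(ss$year, ss[[what]])[, 1:7]
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(scope = sc, scope_type = scopes$scope_type[i],
                     period = sprintf("%d-%d", per[1], per[2]),
                     variable = what),
          tr)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
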