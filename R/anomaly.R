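#' S-H-ESD detection parameters
#'
#' Bundles the tuning parameters of the seasonal hybrid ESD detector.
#'
#' @param period Days per seasonal cycle; 7 for weekly seasonality in daily
#'   web traffic.
#' @param span_days Length of the piecewise-median trend windows, in days.
#'   The default of 182 (half a year) suits series with only a marginal trend.
#' @param alpha Significance level of the ESD test. The conservative default
#'   0.01 limits flags to meaningful outliers in noisy daily data.
#' @param max_outlier_fraction Upper bound on the number of outliers as a
#'   fraction of the series length; the ESD iteration runs
#'   `floor(max_outlier_fraction * n)` steps.
#' @param direction `"upper"` (default; only days exceeding expectation are
#'   sought), `"lower"`, or `"both"`.
#' @return A validated list of class `shesd_params`.
#' @export
shesd_params <- function(period = 7, span_days = 182, alpha = 0.01,
                         max_outlier_fraction = 0.10,
                         direction = c("upper", "lower", "both")) {
  direction <- match.arg(direction)
  if (!is.numeric(period) || period < 2) abort("`period` must be >= 2 days.")
  if (!is.numeric(span_days) || span_days < period) {
    abort("`span_days` must be at least one seasonal period.")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (!is.numeric(max_outlier_fraction) || max_outlier_fraction <= 0 ||
      max_outlier_fraction > 0.49) {
    abort("`max_outlier_fraction` must lie in (0, 0.49].")
  }
  structure(
    list(period = as.integer(period), span_days = as.integer(span_days),
         alpha = alpha, max_outlier_fraction = max_outlier_fraction,
         direction = direction),
    class = "shesd_params"
  )
}

#' Robust periodic seasonal component
#'
#' Estimates a periodic additive seasonal component: observations are
#' detrended with a centered running median one period wide, the median of the
#' detrended values at each phase (e.g. weekday) is taken, and the phase
#' effects are re-centered to sum to zero over one period. The component is
#' constant across cycles.
#'
#' @param values Numeric vector, one value per consecutive day.
#' @param period Days per cycle.
#' @return Numeric vector of the same length as `values`.
#' @export
seasonal_estimate <- function(values, period = 7) {
  n <- length(values)
  if (n < 2 * period) {
    abort("Seasonal estimation needs at least two full periods of data.")
  }
  width <- if (period %% 2 == 1) period else period + 1
  detrended <- values - runmed(values, width, endrule = "median")
  phase <- (seq_len(n) - 1L) %% period
  phase_med <- vapply(
    split(detrended, phase), median, numeric(1), na.rm = TRUE
  )
  phase_effect <- phase_med - mean(phase_med)
  unname(phase_effect[as.character(phase)])
}

#' Piecewise-median trend component
#'
#' Partitions the series into consecutive windows of `span_days` anchored at
#' the series start; the trend on each day is the median of the series within
#' its window. A trailing partial window shorter than `span_days / 2` is
#' merged into the preceding window (a handful of leftover days would make a
#' statistically meaningless median span); a longer one stands alone.
#'
#' @param values Numeric vector (typically the deseasonalized series).
#' @param span_days Window length in days.
#' @return Numeric vector of window medians, one per day.
#' @export
piecewise_median_trend <- function(values, span_days = 182) {
  n <- length(values)
  if (!is.numeric(span_days) || span_days < 1) abort("`span_days` must be >= 1.")
  span_days <- as.integer(span_days)
  window <- pmin((seq_len(n) - 1L) %/% span_days + 1L, max(1L, n %/% span_days))
  remainder <- n %% span_days
  if (remainder > 0 && remainder >= span_days / 2) {
    window[seq.int(n - remainder + 1L, n)] <- max(window) + 1L
  }
  meds <- vapply(split(values, window), median, numeric(1), na.rm = TRUE)
  unname(meds[as.character(window)])
}

#' Robust additive decomposition of a daily series
#'
#' Decomposes a contiguous daily series into a periodic seasonal component
#' (per-phase medians, [seasonal_estimate()]), a piecewise-median trend of the
#' deseasonalized series ([piecewise_median_trend()]), and a remainder defined
#' as `observed - seasonal - trend`, so the additive identity holds to machine
#' precision by construction.
#'
#' @param series A `daily_series` tibble (`date`, `views`) or any data frame
#'   with a date column and a numeric value column in that order.
#' @param period Days per seasonal cycle.
#' @param span_days Piecewise-median window length.
#' @return A tibble of class `shesd_decomposition` with columns `date`,
#'   `observed`, `seasonal`, `trend`, `remainder`.
#' @export
shesd_decompose <- function(series, period = 7, span_days = 182) {
  series <- as_daily_series(series)
  x <- series$views
  seasonal <- seasonal_estimate(x, period)
  trend <- piecewise_median_trend(x - seasonal, span_days)
  out <- tibble::tibble(
    date = series$date,
    observed = x,
    seasonal = seasonal,
    trend = trend,
    remainder = x - seasonal - trend
  )
  class(out) <- c("shesd_decomposition", class(out))
  attr(out, "period") <- as.integer(period)
  attr(out, "span_days") <- as.integer(span_days)
  out
}

as_daily_series <- function(series) {
  if (is.numeric(series)) {
    abort("`series` must carry dates; supply a tibble with `date` and `views`.")
  }
  series <- tibble::as_tibble(series)
  if (!all(c("date", "views") %in% names(series))) {
    names(series)[1:2] <- c("date", "views")
  }
  series$date <- as.Date(series$date)
  if (anyNA(series$date) || anyNA(series$views)) {
    abort("Daily series contains missing dates or values.")
  }
  if (nrow(series) > 1 &&
      !all(diff(series$date) == 1)) {
    abort("Daily series must be contiguous (one row per consecutive day).")
  }
  series
}

#' ESD critical value
#'
#' Critical value of the generalized (extreme studentized deviate) test at
#' removal step `k`:
#' `lambda_k = (n - k) * t / sqrt((n - k - 1 + t^2) * (n - k + 1))` with `t`
#' the `p` quantile of a Student t on `n - k - 1` degrees of freedom, where
#' `p = 1 - alpha / (n - k + 1)` one-tailed and
#' `p = 1 - alpha / (2 (n - k + 1))` two-tailed.
#'
#' @param n Series length.
#' @param k Removal step (vectorized).
#' @param alpha Significance level.
#' @param direction `"upper"`/`"lower"` (one-tailed) or `"both"` (two-tailed).
#' @return Numeric vector of critical values.
#' @export
esd_lambda <- function(n, k, alpha, direction = c("upper", "lower", "both")) {
  direction <- match.arg(direction)
  df <- n - k - 1
  if (any(df < 1)) abort("Degenerate ESD step: need n - k - 1 >= 1.")
  p <- if (direction == "both") 1 - alpha / (2 * (n - k + 1)) else 1 - alpha / (n - k + 1)
  t <- qt(p, df)
  (n - k) * t / sqrt((df + t^2) * (n - k + 1))
}

#' Robust generalized ESD outlier test
#'
#' Iteratively studentizes the most extreme remaining value against the median
#' and the (normal-consistent, 1.4826-scaled) median absolute deviation of the
#' values not yet removed, removes it, and after `k_max` steps reports as
#' outliers the first `k*` removals, where `k*` is the largest step whose
#' statistic exceeded its critical value. Using median/MAD instead of mean/sd
#' makes the test resistant to masking by gross outliers; `center = "mean"`
#' recovers the classical generalized ESD procedure.
#'
#' When the MAD is zero the scale falls back to the mean absolute deviation
#' from the median; if that is also zero the values are essentially constant
#' and no outliers are reported (with a warning).
#'
#' @param residuals Numeric vector to test (typically decomposition
#'   remainders).
#' @param alpha Significance level.
#' @param k_max Maximum number of outliers to consider.
#' @param direction `"upper"`, `"lower"`, or `"both"`.
#' @param center `"median"` (robust, default) or `"mean"` (classical ESD).
#' @return A tibble with one row per removal step: `k`, `index`, `value`,
#'   `stat` (C_k), `lambda` (critical value), `outlier` (logical). Ties in the
#'   extremum are broken by earliest index.
#' @export
robust_esd <- function(residuals, alpha = 0.01, k_max,
                       direction = c("upper", "lower", "both"),
                       center = c("median", "mean")) {
  direction <- match.arg(direction)
  center <- match.arg(center)
  n <- length(residuals)
  if (!is.numeric(k_max) || k_max < 1) abort("`k_max` must be >= 1.")
  k_max <- as.integer(k_max)
  if (n <= k_max + 2) abort("Series too short for the requested `k_max`.")

  remaining <- seq_len(n)
  ks <- integer(0); idx <- integer(0); val <- numeric(0); stat <- numeric(0)
  for (k in seq_len(k_max)) {
    vals <- residuals[remaining]
    if (center == "median") {
      ctr <- median(vals)
      sc <- mad(vals)
      if (sc == 0) sc <- mean(abs(vals - ctr))
    } else {
      ctr <- mean(vals)
      sc <- stats::sd(vals)
    }
    if (!is.finite(sc) || sc == 0) {
      if (k == 1L) warn("Residual scale is zero; no outliers can be tested.")
      break
    }
    dev <- switch(direction,
      upper = vals - ctr,
      lower = ctr - vals,
      both = abs(vals - ctr)
    )
    i_loc <- which.max(dev / sc)  # first max: earliest index wins ties
    ks <- c(ks, k)
    idx <- c(idx, remaining[i_loc])
    val <- c(val, vals[i_loc])
    stat <- c(stat, dev[i_loc] / sc)
    remaining <- remaining[-i_loc]
  }
  if (length(ks) == 0) {
    return(tibble::tibble(k = integer(0), index = integer(0),
                          value = numeric(0), stat = numeric(0),
                          lambda = numeric(0), outlier = logical(0)))
  }
  lambda <- esd_lambda(n, ks, alpha, direction)
  exceed <- which(stat > lambda)
  k_star <- if (length(exceed) == 0) 0L else max(exceed)
  tibble::tibble(k = ks, index = idx, value = val, stat = stat,
                 lambda = lambda, outlier = ks <= k_star)
}

#' Seasonal hybrid ESD outlier detection
#'
#' Runs the full S-H-ESD pipeline on a univariate daily series: robust
#' additive decomposition ([shesd_decompose()]), then the median/MAD
#' generalized ESD test ([robust_esd()]) on the remainders with
#' `k_max = floor(max_outlier_fraction * n)`. Flagged steps are mapped back
#' to calendar days with observed and expected (seasonal + trend) values.
#'
#' @param series A `daily_series` tibble (`date`, `views`).
#' @param params A [shesd_params()] object.
#' @return An object of class `shesd`: a list with elements `series`,
#'   `decomposition`, `params`, `candidates` (every ESD step), and `outliers`
#'   (flagged days, in detection order). Use [tidy()] for the outlier table,
#'   [glance()] for a one-row summary, and [autoplot()] for an annotated plot.
#' @export
#' @examples
#' sim <- gen_pageview_panel(panel_spec(n_days = 400), seed = 1)
#' fit <- shesd_detect(aggregate_daily_total(sim$panel))
#' glance(fit)
shesd_detect <- function(series, params = shesd_params()) {
  stopifnot(inherits(params, "shesd_params"))
  series <- as_daily_series(series)
  n <- nrow(series)
  dec <- shesd_decompose(series, params$period, params$span_days)
  k_max <- floor(params$max_outlier_fraction * n)
  if (k_max < 1) abort("Series too short: `max_outlier_fraction * n` is below 1.")
  candidates <- robust_esd(dec$remainder, alpha = params$alpha, k_max = k_max,
                           direction = params$direction)
  flagged <- dplyr::filter(candidates, .data$outlier)
  outliers <- tibble::tibble(
    date = dec$date[flagged$index],
    observed = dec$observed[flagged$index],
    expected = dec$seasonal[flagged$index] + dec$trend[flagged$index],
    residual = dec$remainder[flagged$index],
    stat = flagged$stat,
    lambda = flagged$lambda,
    k = flagged$k
  )
  structure(
    list(series = series, decomposition = dec, params = params,
         candidates = candidates, outliers = outliers),
    class = "shesd"
  )
}

#' @export
print.shesd <- function(x, ...) {
  cat("Seasonal hybrid ESD detection\n")
  cat("  n =", nrow(x$series), "days;", nrow(x$outliers), "outlying day(s)\n")
  cat("  period =", x$params$period, "| span =", x$params$span_days,
      "| alpha =", x$params$alpha, "| direction =", x$params$direction, "\n")
  invisible(x)
}

#' @rdname shesd_detect
#' @param x An `shesd` fit.
#' @param ... Unused.
#' @export
tidy.shesd <- function(x, ...) {
  dplyr::arrange(x$outliers, .data$date)
}

#' @rdname shesd_detect
#' @export
glance.shesd <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$series),
    n_outliers = nrow(x$outliers),
    max_stat = if (nrow(x$candidates) > 0) max(x$candidates$stat) else NA_real_,
    period = x$params$period,
    span_days = x$params$span_days,
    alpha = x$params$alpha,
    direction = x$params$direction
  )
}

#' Breusch-Pagan heteroscedasticity diagnostic
#'
#' Tests the null hypothesis of constant residual variance by regressing the
#' squared residuals on the fitted values; the Lagrange-multiplier statistic
#' is `n * R^2` of that auxiliary regression, compared to a chi-squared
#' distribution with one degree of freedom.
#'
#' @param residuals Numeric vector of residuals.
#' @param fitted Numeric vector of fitted values (same length, not constant).
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
breusch_pagan <- function(residuals, fitted) {
  n <- length(residuals)
  if (length(fitted) != n || n < 3) {
    abort("`residuals` and `fitted` must have equal length >= 3.")
  }
  if (max(fitted) == min(fitted)) {
    abort("`fitted` is constant; the auxiliary regression is undefined.")
  }
  aux <- lm(I(residuals^2) ~ fitted)
  r2 <- summary(aux)$r.squared
  stat <- n * r2
  tibble::tibble(statistic = stat, df = 1,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
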