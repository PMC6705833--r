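#' Merge calendar-consecutive dates into runs
#'
#' Sequential outlying days are treated as one temporal period (an epoch).
#' "Consecutive" means adjacent calendar days: a gap of two or more days
#' starts a new run.
#'
#' @param dates A vector of unique `Date`s (any order).
#' @return A tibble with one row per maximal run, chronologically ordered:
#'   `start`, `end` (inclusive), `n_days`.
#' @export
merge_consecutive_dates <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) abort("`dates` contains unparseable values.")
  if (anyDuplicated(dates)) abort("`dates` must be unique.")
  if (length(dates) == 0) {
    return(tibble::tibble(start = as.Date(character(0)),
                          end = as.Date(character(0)), n_days = integer(0)))
  }
  d <- sort(dates)
  run <- cumsum(c(1L, as.integer(diff(d) > 1)))
  tibble::tibble(date = d, run = run) |>
    dplyr::summarise(start = min(.data$date), end = max(.data$date),
                     n_days = dplyr::n(), .by = "run") |>
    dplyr::select(!"run")
}

#' Build ranked outlying epochs from flagged days
#'
#' Merges the flagged dates into maximal consecutive runs, attaches the peak
#' observed pageview count (and its date) within each run, ranks epochs by
#' descending peak (ties broken by earlier start date), and appends the
#' media-correlate search window of each epoch.
#'
#' @param outliers Flagged days: a `Date` vector, a tibble with a `date`
#'   column (e.g. `tidy()` of an `shesd` fit), or an `shesd` fit.
#' @param series The `daily_series` tibble (`date`, `views`) the outliers
#'   were detected in; every flagged date must lie inside it.
#' @return A tibble of class `epoch_set`, chronologically ordered, with
#'   columns `epoch`, `start`, `end`, `n_days`, `peak_views`, `peak_date`,
#'   `rank`, `window_start`, `window_end`.
#' @export
build_epochs <- function(outliers, series) {
  if (inherits(outliers, "shesd")) outliers <- outliers$outliers
  if (is.data.frame(outliers)) outliers <- outliers$date
  dates <- as.Date(outliers)
  series <- as_daily_series(series)
  if (!all(dates %in% series$date)) {
    abort("Some outlier dates fall outside the series date range.")
  }
  runs <- merge_consecutive_dates(dates)
  peaks <- purrr::pmap(runs, function(start, end, n_days) {
    member <- dplyr::filter(series, .data$date >= start, .data$date <= end)
    i <- which.max(member$views)
    tibble::tibble(peak_views = member$views[i], peak_date = member$date[i])
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(runs, peaks) |>
    dplyr::mutate(
      rank = rank_by_peak(.data$peak_views, .data$start),
      epoch = dplyr::row_number()
    ) |>
    dplyr::bind_cols(media_window(runs)) |>
    dplyr::select("epoch", "start", "end", "n_days", "peak_views",
                  "peak_date", "rank", "window_start", "window_end")
  class(out) <- c("epoch_set", class(out))
  out
}

# Rank 1 = highest peak; ties go to the earlier start date.
rank_by_peak <- function(peak, start) {
  order(order(-peak, start))
}

#' Media-correlate search window of an epoch
#'
#' The day before and the day after each epoch are included to absorb time
#' zone differences and lagged coverage effects: the window is
#' (start - 1 day, end + 1 day).
#'
#' @param epochs A tibble with `start` and `end` `Date` columns (e.g. from
#'   [merge_consecutive_dates()] or [build_epochs()]).
#' @return A tibble with columns `window_start`, `window_end`, one row per
#'   epoch.
#' @export
media_window <- function(epochs) {
  tibble::tibble(
    window_start = as.Date(epochs$start) - 1L,
    window_end = as.Date(epochs$end) + 1L
  )
}

#' Epoch report table
#'
#' Emits the epoch summary in the layout used for media-correlate review:
#' one chronologically ordered row per epoch with its date range, highest
#' observed pageview count, rank, search window, and an empty correlate
#' column for manual annotation (correlate identification is a human step).
#' Input order is normalized, so shuffled epochs yield an identical report.
#'
#' @param epochs An `epoch_set` from [build_epochs()].
#' @param path Optional CSV output path.
#' @return The report tibble (invisibly returns `path` written if given).
#' @export
epoch_report <- function(epochs, path = NULL) {
  if (nrow(epochs) == 0) abort("`epochs` is empty.")
  report <- epochs |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$start) |>
    dplyr::mutate(
      epoch = dplyr::row_number(),
      dates = format_date_span(.data$start, .data$end),
      media_window = format_date_span(.data$window_start, .data$window_end),
      potential_correlates = ""
    ) |>
    dplyr::select("epoch", "dates", highest_observed_pageview = "peak_views",
                  "rank", "media_window", "potential_correlates")
  if (!is.null(path)) readr::write_csv(report, path)
  report
}

# M/D/YYYY spans; single days collapse to one date.
format_date_span <- function(start, end) {
  fmt <- function(d) {
    lt <- as.POSIXlt(as.Date(d))
    paste(lt$mon + 1, lt$mday, lt$year + 1900, sep = "/")
  }
  ifelse(start == end, fmt(start), paste0(fmt(start), "–", fmt(end)))
}
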