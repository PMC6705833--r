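#' Pageview panels
#'
#' A pageview panel is a long tibble of daily view counts with columns
#' `date`, `page`, `language`, and `views`, carrying its inclusive study
#' `date_range` as an attribute. Combinations of (date, page, language) that
#' are absent are interpreted as zero views, matching the Langviews convention
#' of omitting zero-traffic days.
#'
#' @param records A data frame with columns `date` (Date), `page` (character),
#'   `language` (character), and `views` (non-negative numeric).
#' @param date_range Optional length-2 Date vector (first day, last day,
#'   inclusive). Defaults to the range of dates present in `records`.
#' @return A tibble of class `pageview_panel`.
#' @export
pageview_panel <- function(records, date_range = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("date", "page", "language", "views")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel records lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records$date <- as.Date(records$date)
  if (any(is.na(records$date))) abort("Panel records contain unparseable dates.")
  if (any(is.na(records$views) | records$views < 0)) {
    abort("Panel records contain missing or negative view counts.")
  }
  if (is.null(date_range)) {
    if (nrow(records) == 0) abort("Cannot infer a date range from an empty panel.")
    date_range <- range(records$date)
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[1] > date_range[2]) {
    abort("`date_range` must be two ordered, valid dates.")
  }
  if (nrow(records) > 0 &&
      (min(records$date) < date_range[1] || max(records$date) > date_range[2])) {
    abort("Panel records fall outside the declared date range.")
  }
  dup <- records |>
    dplyr::distinct() |>
    dplyr::count(.data$date, .data$page, .data$language) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Conflicting duplicate counts for ", dup$language[1], " on ",
                 format(dup$date[1]), "."))
  }
  out <- dplyr::distinct(records[required]) |>
    dplyr::arrange(.data$date, .data$page, .data$language)
  attr(out, "date_range") <- date_range
  class(out) <- c("pageview_panel", class(tibble::tibble()))
  out
}

#' @rdname pageview_panel
#' @param panel A `pageview_panel`.
#' @export
panel_date_range <- function(panel) {
  rng <- attr(panel, "date_range")
  if (is.null(rng)) rng <- range(as.Date(panel$date))
  as.Date(rng)
}

# Dates arrive either ISO (2016-06-04) or US-style (6/4/2016); supplementary
# spreadsheets also substitute en/em dashes for hyphens.
parse_flex_date <- function(x) {
  x <- stringr::str_trim(stringr::str_replace_all(x, "[–—]", "-"))
  out <- as.Date(x, format = "%Y-%m-%d")
  us <- is.na(out)
  out[us] <- as.Date(x[us], format = "%m/%d/%Y")
  out
}

# Counts may carry thousands separators; negatives are never valid pageviews.
parse_count <- function(x, rows = seq_along(x)) {
  cleaned <- stringr::str_replace_all(stringr::str_trim(x), "[,  ]", "")
  n <- suppressWarnings(as.numeric(cleaned))
  bad <- which(is.na(n) | n < 0)
  if (length(bad) > 0) {
    abort(paste0("Unparseable or negative view count ('", x[bad[1]],
                 "') at data row ", rows[bad[1]], "."))
  }
  n
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) abort(paste0("'", path, "' is empty."))
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_delim_chr <- function(path) {
  if (!file.exists(path)) abort(paste0("Input file '", path, "' does not exist."))
  readr::read_delim(
    path, delim = sniff_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE
  )
}

#' Read a Langviews-style pageview export
#'
#' Accepts both export layouts, auto-detected from the header: long
#' (`date`, `language`, `views` columns, names matched case-insensitively)
#' and wide (one row per language, one column per date). Dates may be ISO or
#' M/D/YYYY; thousands separators in counts are stripped.
#'
#' @param path Path to a CSV/TSV export.
#' @param page_label Page title to attach to every record (e.g. `"Sepsis"`).
#' @return A [pageview_panel()] covering exactly the dates present in the file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("date,language,views",
#'              "2016-06-04,en,100",
#'              "2016-06-04,ja,50"), f)
#' read_langviews(f, "Sepsis")
read_langviews <- function(path, page_label) {
  raw <- read_delim_chr(path)
  if (nrow(raw) == 0) abort(paste0("'", path, "' holds no data rows."))
  lowered <- tolower(names(raw))
  date_col <- which(lowered %in% c("date", "day"))
  lang_col <- which(lowered %in% c("language", "lang", "locale", "wiki"))
  views_col <- which(lowered %in% c("views", "count", "pageviews", "views_sum"))
  header_dates <- parse_flex_date(names(raw))

  if (length(date_col) == 1 && length(lang_col) == 1 && length(views_col) == 1) {
    dates <- parse_flex_date(raw[[date_col]])
    if (anyNA(dates)) {
      abort(paste0("Unparseable date ('", raw[[date_col]][which(is.na(dates))[1]],
                   "') at data row ", which(is.na(dates))[1], "."))
    }
    records <- tibble::tibble(
      date = dates,
      page = page_label,
      language = raw[[lang_col]],
      views = parse_count(raw[[views_col]])
    )
  } else if (sum(!is.na(header_dates)) >= 2) {
    lang_col <- if (length(lang_col) == 1) lang_col else 1L
    keep <- which(!is.na(header_dates))
    long <- tidyr::pivot_longer(
      raw[c(lang_col, keep)],
      cols = -1, names_to = "date_label", values_to = "views_label"
    )
    long <- dplyr::filter(long, !is.na(.data$views_label), .data$views_label != "")
    records <- tibble::tibble(
      date = parse_flex_date(long$date_label),
      page = page_label,
      language = long[[1]],
      views = parse_count(long$views_label)
    )
  } else {
    abort(paste0("'", path, "' matches neither the long (date, language, views) ",
                 "nor the wide (language x date) Langviews layout."))
  }
  pageview_panel(records)
}

#' Write a pageview panel
#'
#' The canonical output is the long layout (`date`, `page`, `language`,
#' `views`) with ISO dates; the wide layout (one row per language, one column
#' per ISO date) mirrors the spreadsheet-style exports and round-trips through
#' [read_langviews()].
#'
#' @param panel A [pageview_panel()].
#' @param path Output file path (CSV).
#' @param layout `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_langviews <- function(panel, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    out <- dplyr::mutate(tibble::as_tibble(panel), date = format(.data$date))
    readr::write_csv(out, path)
  } else {
    wide <- panel |>
      tibble::as_tibble() |>
      dplyr::mutate(date = format(.data$date)) |>
      dplyr::select("language", "date", "views") |>
      tidyr::pivot_wider(names_from = "date", values_from = "views")
    readr::write_csv(wide, path)
  }
  invisible(path)
}

#' Collapse pageview panels to a univariate daily total series
#'
#' Sums views over all pages and languages, one value per calendar day of the
#' shared date range, with absent combinations counted as zero.
#'
#' @param panels A single [pageview_panel()] or a list of them.
#' @param zero_fill If `TRUE`, panels with differing date ranges are reindexed
#'   onto the union range with zero fill; if `FALSE` (default) a range
#'   mismatch is an error.
#' @return A tibble of class `daily_series` with columns `date` and `views`,
#'   one row per day.
#' @export
aggregate_daily_total <- function(panels, zero_fill = FALSE) {
  if (inherits(panels, "pageview_panel")) panels <- list(panels)
  if (!is.list(panels) || length(panels) == 0) {
    abort("`panels` must be a pageview panel or a nonempty list of them.")
  }
  ranges <- lapply(panels, panel_date_range)
  same <- all(vapply(ranges, function(r) identical(r, ranges[[1]]), logical(1)))
  if (!same && !zero_fill) {
    abort("Panels cover different date ranges; set `zero_fill = TRUE` to sum over the union.")
  }
  lo <- min(as.Date(unlist(lapply(ranges, `[`, 1), use.names = FALSE)))
  hi <- max(as.Date(unlist(lapply(ranges, `[`, 2), use.names = FALSE)))
  days <- tibble::tibble(date = seq(lo, hi, by = "day"))
  totals <- panels |>
    purrr::map(tibble::as_tibble) |>
    purrr::list_rbind() |>
    dplyr::summarise(views = sum(.data$views), .by = "date")
  out <- days |>
    dplyr::left_join(totals, by = "date") |>
    dplyr::mutate(views = dplyr::coalesce(.data$views, 0))
  class(out) <- c("daily_series", class(out))
  out
}

#' Per-language pageview totals and shares
#'
#' Totals views per language across one or more panels, ranks languages by
#' total, and folds ranks beyond `top_k` into an `"Other"` bucket. Shares are
#' fractions of the grand total; totals are conserved exactly.
#'
#' @inheritParams aggregate_daily_total
#' @param top_k Number of languages to keep before folding into `other_label`.
#' @param other_label Label of the rollup bucket.
#' @return A tibble with columns `language`, `views`, `share`, ranked
#'   descending, the rollup bucket (if any) last.
#' @export
language_shares <- function(panels, top_k = 15, other_label = "Other") {
  if (!is.numeric(top_k) || length(top_k) != 1 || is.na(top_k) || top_k < 1) {
    abort("`top_k` must be a single integer >= 1.")
  }
  if (inherits(panels, "pageview_panel")) panels <- list(panels)
  if (length(panels) == 0) abort("`panels` must be nonempty.")
  totals <- panels |>
    purrr::map(tibble::as_tibble) |>
    purrr::list_rbind() |>
    dplyr::summarise(views = sum(.data$views), .by = "language") |>
    dplyr::arrange(dplyr::desc(.data$views), .data$language)
  grand <- sum(totals$views)
  kept <- head(totals, top_k)
  rest <- totals[-seq_len(min(top_k, nrow(totals))), , drop = FALSE]
  if (nrow(rest) > 0) {
    kept <- dplyr::bind_rows(
      kept, tibble::tibble(language = other_label, views = sum(rest$views))
    )
  }
  dplyr::mutate(kept, share = .data$views / grand)
}

#' Read a Massviews-style category export
#'
#' Parses a delimited file of per-page totals for a page category (e.g.
#' critical care), for share-of-category computations.
#'
#' @param path Path to a CSV/TSV of (page title, total views).
#' @return A tibble with columns `page` and `views`.
#' @export
read_massviews <- function(path) {
  raw <- read_delim_chr(path)
  if (nrow(raw) == 0) abort(paste0("'", path, "' holds no data rows."))
  lowered <- tolower(names(raw))
  page_col <- which(lowered %in% c("page", "title", "article", "page_title"))
  views_col <- which(lowered %in% c("views", "count", "total", "pageviews"))
  page_col <- if (length(page_col) >= 1) page_col[1] else 1L
  views_col <- if (length(views_col) >= 1) views_col[1] else 2L
  tibble::tibble(
    page = raw[[page_col]],
    views = parse_count(raw[[views_col]])
  )
}

#' Share of a category's pageviews held by target pages
#'
#' @param totals A per-page totals tibble from [read_massviews()].
#' @param target_pages Character vector of page titles (underscore/space
#'   variants are matched).
#' @return The targets' fraction of the category grand total.
#' @export
category_share <- function(totals, target_pages) {
  if (nrow(totals) == 0) abort("Category totals are empty.")
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  hit <- norm(totals$page) %in% norm(target_pages)
  sum(totals$views[hit]) / sum(totals$views)
}

#' Write a daily total series as CSV with ISO dates
#'
#' @param series A `daily_series` tibble (`date`, `views`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_total <- function(series, path) {
  out <- tibble::tibble(date = format(as.Date(series$date)), views = series$views)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a daily total series written by [write_daily_total()]
#'
#' @param path Input path.
#' @return A `daily_series` tibble.
#' @export
read_daily_total <- function(path) {
  raw <- read_delim_chr(path)
  out <- tibble::tibble(
    date = parse_flex_date(raw[[1]]),
    views = parse_count(raw[[2]])
  )
  if (anyNA(out$date)) abort(paste0("Unparseable date in '", path, "'."))
  class(out) <- c("daily_series", class(out))
  out
}
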