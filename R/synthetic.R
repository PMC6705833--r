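#' Specification of a synthetic pageview panel
#'
#' Describes a multi-language daily pageview panel with weekly seasonality,
#' slow piecewise drift, overdispersed count noise, and injected spike
#' anomalies with known truth. The defaults mimic the scale of real
#' sepsis-page traffic: about 18,756 mean daily views over 1,096 days across
#' 15 named language editions plus an aggregate tail, English dominant.
#'
#' @param start First day of the panel.
#' @param n_days Number of consecutive days.
#' @param shares Named numeric vector of per-language share of traffic
#'   (positive, summing to 1).
#' @param mean_daily_views Long-run mean of the daily total.
#' @param weekday_multipliers Length-7 multipliers (Mon..Sun) shaping the
#'   additive weekly cycle; internally converted to zero-sum additive offsets.
#'   The default gives weekdays a few percent above, weekends ~10% below.
#' @param trend_multipliers Multipliers of `mean_daily_views`, one per
#'   consecutive `trend_span`-day window, giving a slow piecewise drift.
#' @param trend_span Days per trend level.
#' @param noise `"nbinom"` (overdispersed counts, default), `"lognormal"`
#'   (multiplicative misspecification check), or `"none"` (exact means).
#' @param dispersion Negative-binomial size per language-day (smaller =
#'   more overdispersed).
#' @param sigma_log Log-scale sd for `noise = "lognormal"`.
#' @param n_anomalies Number of injected spikes when `anomalies` is `NULL`.
#' @param anomaly_magnitude Spike height in units of the daily-total noise
#'   standard deviation (added to the expected total on spike days).
#' @param anomaly_duration Days per injected spike.
#' @param anomalies Optional explicit tibble (`date`, `duration`,
#'   `magnitude`) overriding the random placement.
#' @return A validated list of class `panel_spec`.
#' @export
panel_spec <- function(start = as.Date("2015-07-01"),
                       n_days = 1096,
                       shares = default_language_shares(),
                       mean_daily_views = 18756,
                       weekday_multipliers = c(1.05, 1.06, 1.05, 1.04, 1.00, 0.90, 0.90),
                       trend_multipliers = c(0.95, 1.00, 1.06, 1.02, 0.97, 1.00),
                       trend_span = 182,
                       noise = c("nbinom", "lognormal", "none"),
                       dispersion = 50,
                       sigma_log = 0.05,
                       n_anomalies = 10,
                       anomaly_magnitude = 8,
                       anomaly_duration = 1,
                       anomalies = NULL) {
  noise <- match.arg(noise)
  start <- as.Date(start)
  if (is.na(start)) abort("`start` must be a valid date.")
  if (!is.numeric(n_days) || n_days < 14) abort("`n_days` must be >= 14.")
  if (is.null(names(shares)) || any(shares <= 0)) {
    abort("`shares` must be a named vector of positive language shares.")
  }
  if (abs(sum(shares) - 1) > 1e-8) abort("`shares` must sum to 1.")
  if (length(weekday_multipliers) != 7) {
    abort("`weekday_multipliers` must have length 7 (Mon..Sun).")
  }
  if (!is.null(anomalies)) {
    anomalies <- tibble::as_tibble(anomalies)
    anomalies$date <- as.Date(anomalies$date)
    if (!"duration" %in% names(anomalies)) anomalies$duration <- 1L
    if (!"magnitude" %in% names(anomalies)) anomalies$magnitude <- anomaly_magnitude
    end <- start + n_days - 1
    if (any(anomalies$date < start | anomalies$date + anomalies$duration - 1 > end)) {
      abort("Injected anomalies must lie inside the panel date range.")
    }
  }
  structure(
    list(start = start, n_days = as.integer(n_days), shares = shares,
         mean_daily_views = mean_daily_views,
         weekday_multipliers = weekday_multipliers,
         trend_multipliers = trend_multipliers,
         trend_span = as.integer(trend_span), noise = noise,
         dispersion = dispersion, sigma_log = sigma_log,
         n_anomalies = as.integer(n_anomalies),
         anomaly_magnitude = anomaly_magnitude,
         anomaly_duration = as.integer(anomaly_duration),
         anomalies = anomalies),
    class = "panel_spec"
  )
}

#' @rdname panel_spec
#' @export
default_language_shares <- function() {
  major <- c(en = 0.431, ja = 0.101, ru = 0.080, de = 0.070, es = 0.060,
             it = 0.051)
  minor_names <- c("fr", "pt", "zh", "pl", "nl", "ar", "ko", "tr", "fa", "other")
  w <- 1 / seq_along(minor_names)
  minor <- (1 - sum(major)) * w / sum(w)
  names(minor) <- minor_names
  c(major, minor)
}

# Deterministic per-day expected components of the daily total.
spec_components <- function(spec) {
  dates <- seq(spec$start, by = "day", length.out = spec$n_days)
  wd <- as.POSIXlt(dates)$wday          # 0 = Sunday
  mon_first <- ifelse(wd == 0, 7L, wd)  # 1 = Monday .. 7 = Sunday
  offsets <- (spec$weekday_multipliers - mean(spec$weekday_multipliers)) *
    spec$mean_daily_views
  seasonal <- offsets[mon_first]
  win <- pmin((seq_len(spec$n_days) - 1L) %/% spec$trend_span + 1L,
              length(spec$trend_multipliers))
  trend <- spec$mean_daily_views * spec$trend_multipliers[win]
  list(dates = dates, seasonal = seasonal, trend = trend,
       expected_total = trend + seasonal)
}

#' Analytic noise scale of the synthetic daily total
#'
#' For negative-binomial noise the variance of the daily total is
#' `sum_l(mu_l + mu_l^2 / dispersion)` over languages; the day-averaged
#' standard deviation calibrates injected spike magnitudes.
#'
#' @param spec A [panel_spec()].
#' @return The standard deviation of the daily total under the spec's noise
#'   model (0 for `noise = "none"`).
#' @export
panel_noise_sd <- function(spec) {
  comp <- spec_components(spec)
  mu_day <- mean(comp$expected_total)
  mu_l <- spec$shares * mu_day
  switch(spec$noise,
    nbinom = sqrt(sum(mu_l + mu_l^2 / spec$dispersion)),
    lognormal = sqrt(sum(mu_l^2 * (exp(spec$sigma_log^2) - 1))),
    none = 0
  )
}

#' Generate a synthetic pageview panel with known truth
#'
#' Draws per-language daily counts around the spec's additive
#' seasonal-plus-trend mean structure, superimposes the injected spike
#' anomalies (added to the dominant language's expected count before noise),
#' and records the ground truth needed to score any downstream detector.
#' Output is bit-reproducible for a fixed (spec, seed) pair, and the caller's
#' RNG state is left untouched.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed.
#' @return A list with elements `panel` (a [pageview_panel()]), `truth` (a
#'   list: `anomalies` tibble with per-spike `date`, `duration`, `magnitude`,
#'   `added_views`; `anomaly_dates`; per-day `seasonal`, `trend`,
#'   `expected_total`; `noise_sd`), `spec`, and `seed`.
#' @export
gen_pageview_panel <- function(spec = panel_spec(), seed) {
  stopifnot(inherits(spec, "panel_spec"))
  comp <- spec_components(spec)
  sd_total <- panel_noise_sd(spec)
  with_seed(seed, {
    anomalies <- spec$anomalies
    if (is.null(anomalies) && spec$n_anomalies > 0) {
      anomalies <- place_anomalies(comp$dates, spec$n_anomalies,
                                   spec$anomaly_duration, spec$anomaly_magnitude)
    }
    if (is.null(anomalies)) {
      anomalies <- tibble::tibble(date = as.Date(character(0)),
                                  duration = integer(0), magnitude = numeric(0))
    }
    spike_scale <- if (sd_total > 0) sd_total else sqrt(spec$mean_daily_views)
    anomalies$added_views <- anomalies$magnitude * spike_scale
    anomaly_dates <- unique(as.Date(unlist(purrr::pmap(
      anomalies[c("date", "duration")],
      function(date, duration) seq(date, by = "day", length.out = duration)
    ), use.names = FALSE), origin = "1970-01-01"))
    spike <- numeric(spec$n_days)
    for (i in seq_len(nrow(anomalies))) {
      days <- match(seq(anomalies$date[i], by = "day",
                        length.out = anomalies$duration[i]), comp$dates)
      spike[days] <- spike[days] + anomalies$added_views[i]
    }
    top_lang <- names(spec$shares)[which.max(spec$shares)]
    records <- purrr::imap(spec$shares, function(share, lang) {
      mu <- share * comp$expected_total
      if (lang == top_lang) mu <- mu + spike
      views <- switch(spec$noise,
        nbinom = rnbinom(spec$n_days, size = spec$dispersion, mu = mu),
        lognormal = mu * exp(rnorm(spec$n_days, 0, spec$sigma_log) -
                               spec$sigma_log^2 / 2),
        none = mu
      )
      tibble::tibble(date = comp$dates, page = "SyntheticPage",
                     language = lang, views = as.numeric(views))
    }) |> purrr::list_rbind()
    panel <- pageview_panel(records,
                            date_range = range(comp$dates))
    list(
      panel = panel,
      truth = list(anomalies = anomalies, anomaly_dates = sort(anomaly_dates),
                   seasonal = comp$seasonal, trend = comp$trend,
                   expected_total = comp$expected_total, noise_sd = sd_total),
      spec = spec, seed = as.integer(seed)
    )
  })
}

# Random non-overlapping spike placement; starts kept >= 2 days apart so each
# injection is its own epoch, and clear of the series edges.
place_anomalies <- function(dates, n, duration, magnitude) {
  pool <- dates[seq(8, length(dates) - 7 - duration)]
  starts <- as.Date(character(0))
  for (i in seq_len(n)) {
    ok <- pool[vapply(pool, function(d) {
      all(abs(as.numeric(d - starts)) > duration + 1)
    }, logical(1))]
    if (length(ok) == 0) abort("Cannot place the requested number of anomalies.")
    starts <- c(starts, sample(ok, 1))
  }
  tibble::tibble(date = sort(starts), duration = as.integer(duration),
                 magnitude = magnitude)
}

#' Generate a synthetic clickstream with known category totals
#'
#' Draws `n_events` inbound referrals to `target_page` from a multinomial
#' over referrer categories. Reserved categories (those named in
#' [reserved_referrer_categories()]) emit their aggregate token with type
#' `"external"`/`"other"`; ordinary categories are split uniformly (again
#' multinomially) across `pages_per_category` synthetic page titles with type
#' `"link"`. A deterministic power-law set of outbound link edges is drawn
#' from `n_outbound` events so the top-k/outbound path is exercised too.
#'
#' @param proportions Named numeric vector of inbound category proportions
#'   (must sum to 1).
#' @param n_events Total inbound referral count.
#' @param target_page Target page title.
#' @param pages_per_category Synthetic referrer pages per ordinary category.
#' @param n_outbound Total outbound link count (0 to skip).
#' @param n_outbound_pages Number of distinct outbound pages.
#' @param seed Integer seed.
#' @return A list: `edges` (tibble `prev`, `curr`, `type`, `n`, `direction`),
#'   `category_map` (`title`, `category` for the synthetic referrer pages),
#'   and `truth` (list with exact `category_totals` and `outbound_totals`).
#' @export
gen_clickstream <- function(proportions, n_events = 100000,
                            target_page = "Sepsis", pages_per_category = 3,
                            n_outbound = 5000, n_outbound_pages = 12, seed) {
  if (is.null(names(proportions)) || any(proportions < 0)) {
    abort("`proportions` must be a named, non-negative vector.")
  }
  if (abs(sum(proportions) - 1) > 1e-8) abort("`proportions` must sum to 1.")
  reserved <- reserved_referrer_categories()
  with_seed(seed, {
    cat_counts <- drop(rmultinom(1, n_events, proportions))
    edges <- purrr::imap(cat_counts, function(cnt, category) {
      if (cnt == 0) return(NULL)
      tok <- names(reserved)[match(category, reserved)]
      if (!is.na(tok)) {
        tibble::tibble(prev = tok, curr = target_page,
                       type = if (tok %in% c("other-internal", "other-other"))
                         "other" else "external",
                       n = cnt)
      } else {
        pages <- paste0(gsub(" ", "_", category), "_page_",
                        seq_len(pages_per_category))
        per_page <- drop(rmultinom(1, cnt, rep(1, pages_per_category)))
        tibble::tibble(prev = pages, curr = target_page, type = "link",
                       n = per_page)[per_page > 0, ]
      }
    }) |> purrr::list_rbind() |>
      dplyr::mutate(direction = "inbound")
    out_edges <- NULL
    out_truth <- tibble::tibble(page = character(0), n = numeric(0))
    if (n_outbound > 0) {
      out_pages <- paste0("Outbound_topic_", seq_len(n_outbound_pages))
      w <- 1 / seq_len(n_outbound_pages)
      out_counts <- drop(rmultinom(1, n_outbound, w / sum(w)))
      out_edges <- tibble::tibble(prev = target_page, curr = out_pages,
                                  type = "link", n = out_counts,
                                  direction = "outbound")[out_counts > 0, ]
      out_truth <- tibble::tibble(page = out_pages, n = as.numeric(out_counts))
    }
    ordinary <- setdiff(names(proportions), reserved)
    category_map <- tibble::tibble(
      title = unlist(lapply(ordinary, function(category) {
        paste0(gsub(" ", "_", category), "_page_", seq_len(pages_per_category))
      }), use.names = FALSE),
      category = rep(ordinary, each = pages_per_category)
    )
    list(
      edges = dplyr::bind_rows(edges, out_edges),
      category_map = category_map,
      truth = list(
        category_totals = tibble::tibble(category = names(cat_counts),
                                         n = as.numeric(cat_counts)),
        outbound_totals = out_truth
      )
    )
  })
}
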