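# Independent brute-force oracles. These are deliberately written as plain
# loops, separate from the package implementations they check.

# Textbook generalized ESD (Rosner): mean/sd studentization, iterative
# removal, lambda_i from the t distribution.
classical_esd_oracle <- function(x, alpha, k_max, direction = "both") {
  n <- length(x)
  remaining <- x
  idx_remaining <- seq_len(n)
  out_idx <- integer(0)
  R <- numeric(0)
  lam <- numeric(0)
  for (i in seq_len(k_max)) {
    m <- mean(remaining)
    s <- sd(remaining)
    if (s == 0) break
    dev <- switch(direction,
      both = abs(remaining - m),
      upper = remaining - m,
      lower = m - remaining
    )
    j <- which.max(dev / s)
    R[i] <- dev[j] / s
    p <- if (direction == "both") 1 - alpha / (2 * (n - i + 1)) else 1 - alpha / (n - i + 1)
    tq <- qt(p, n - i - 1)
    lam[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    out_idx[i] <- idx_remaining[j]
    remaining <- remaining[-j]
    idx_remaining <- idx_remaining[-j]
  }
  k_star <- 0
  for (i in seq_along(R)) if (R[i] > lam[i]) k_star <- i
  list(indices = out_idx[seq_len(k_star)], R = R, lambda = lam)
}

# Median/MAD variant of the same loop, for spot-checking robust_esd.
robust_esd_oracle <- function(x, alpha, k_max, direction = "upper") {
  n <- length(x)
  remaining <- x
  idx_remaining <- seq_len(n)
  out_idx <- integer(0)
  R <- numeric(0)
  lam <- numeric(0)
  for (i in seq_len(k_max)) {
    ctr <- median(remaining)
    s <- mad(remaining)
    if (s == 0) s <- mean(abs(remaining - ctr))
    if (s == 0) break
    dev <- switch(direction,
      both = abs(remaining - ctr),
      upper = remaining - ctr,
      lower = ctr - remaining
    )
    j <- which.max(dev / s)
    R[i] <- dev[j] / s
    p <- if (direction == "both") 1 - alpha / (2 * (n - i + 1)) else 1 - alpha / (n - i + 1)
    tq <- qt(p, n - i - 1)
    lam[i] <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    out_idx[i] <- idx_remaining[j]
    remaining <- remaining[-j]
    idx_remaining <- idx_remaining[-j]
  }
  k_star <- 0
  for (i in seq_along(R)) if (R[i] > lam[i]) k_star <- i
  sort(out_idx[seq_len(k_star)])
}

# Day-scan run finder: walks the calendar one day at a time.
runs_oracle <- function(dates) {
  if (length(dates) == 0) {
    return(data.frame(start = as.Date(character(0)), end = as.Date(character(0))))
  }
  dates <- sort(dates)
  starts <- as.Date(character(0))
  ends <- as.Date(character(0))
  cur_start <- dates[1]
  day <- dates[1]
  for (d in as.list(dates[-1])) {
    if (as.numeric(d - day) > 1) {
      starts <- c(starts, cur_start); ends <- c(ends, day)
      cur_start <- d
    }
    day <- d
  }
  starts <- c(starts, cur_start); ends <- c(ends, day)
  data.frame(start = starts, end = ends)
}

# Per-day double loop over panel records.
daily_total_oracle <- function(panels) {
  recs <- do.call(rbind, lapply(panels, as.data.frame))
  rng <- range(do.call(c, lapply(panels, viewspike::panel_date_range)))
  days <- seq(rng[1], rng[2], by = "day")
  views <- vapply(days, function(d) sum(recs$views[recs$date == d]), numeric(1))
  data.frame(date = days, views = views)
}

# Random small pageview panel for property tests.
random_panel <- function(n_langs, n_days, start = as.Date("2017-01-01")) {
  dates <- seq(start, by = "day", length.out = n_days)
  grid <- expand.grid(date = dates, language = paste0("l", seq_len(n_langs)))
  keep <- runif(nrow(grid)) < 0.8  # sparse: absent cells mean zero views
  recs <- data.frame(date = grid$date[keep], page = "P",
                     language = as.character(grid$language[keep]),
                     views = rpois(sum(keep), 50))
  viewspike::pageview_panel(recs, date_range = range(dates))
}

write_tmp <- function(lines, ext = ".csv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
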