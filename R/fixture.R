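#' Reference table of outlying sepsis pageview epochs
#'
#' Machine-readable worked example: the 25 outlying epochs of combined
#' sepsis and septic-shock Wikipedia daily pageview traffic between
#' 2015-07-01 and 2018-06-30, each with its inclusive date range, the highest
#' observed daily pageview count within the epoch, and its rank (1 = highest
#' peak). Expanding the ranges yields the 47 individual outlying days;
#' [merge_consecutive_dates()] on those days recovers the 25 epochs, which
#' makes the table a self-contained oracle for the epoch-aggregation rules.
#'
#' @return A tibble with columns `epoch`, `start`, `end`, `peak_views`,
#'   `rank`.
#' @export
#' @examples
#' fx <- sepsis_epoch_fixture()
#' nrow(fx)                              # 25 epochs
#' length(sepsis_outlier_dates())        # 47 outlying days
sepsis_epoch_fixture <- function() {
  spans <- c(
    "12/6/2015", "1/20/2016", "1/26/2016", "3/26/2016",
    "3/29/2016:4/1/2016", "4/4/2016", "6/4/2016:6/13/2016",
    "9/12/2016:9/17/2016", "9/21/2016", "9/28/2016",
    "10/3/2016:10/4/2016", "10/7/2016", "12/3/2016", "3/10/2017",
    "3/16/2017", "7/4/2017", "9/5/2017", "9/11/2017", "9/13/2017",
    "10/21/2017:10/24/2017", "10/30/2017", "11/19/2017", "1/11/2018",
    "1/18/2018:1/19/2018", "3/12/2018"
  )
  peak_views <- c(22657, 25243, 41784, 22000, 92305, 25048, 224927, 38644,
                  24674, 36984, 29553, 23256, 23023, 30768, 28667, 36600,
                  26685, 30664, 25532, 71140, 25030, 21555, 28857, 32630,
                  37142)
  rank <- c(23, 17, 4, 24, 2, 18, 1, 5, 20, 7, 12, 21, 22, 10, 14, 8, 15,
            11, 16, 3, 19, 25, 13, 9, 6)
  parts <- strsplit(spans, ":", fixed = TRUE)
  start <- parse_flex_date(vapply(parts, `[`, character(1), 1))
  end <- parse_flex_date(vapply(parts, function(p) p[length(p)], character(1)))
  tibble::tibble(epoch = seq_along(spans), start = start, end = end,
                 peak_views = peak_views, rank = rank)
}

#' @rdname sepsis_epoch_fixture
#' @export
sepsis_outlier_dates <- function() {
  fx <- sepsis_epoch_fixture()
  sort(as.Date(unlist(
    purrr::map2(fx$start, fx$end, seq, by = "day"),
    use.names = FALSE
  ), origin = "1970-01-01"))
}
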