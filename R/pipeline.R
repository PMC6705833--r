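#' Assemble and validate a pipeline run configuration
#'
#' A run configuration drives the staged pipeline (`run_detect()`,
#' `run_epochs()`, `run_clickstream()`, `run_simulate()`). It can be given as
#' a YAML file or a named list; unknown fields are rejected and referenced
#' input paths are checked at validation time so a run fails before writing
#' any output.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("Config file '", x, "' does not exist."))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) abort("`x` must be a YAML path or a named list.")
  defaults <- list(
    langviews = list(),          # list of list(path =, page =)
    zero_fill = FALSE,
    shesd = list(),              # overrides for shesd_params()
    top_k_languages = 15,
    top_k_outbound = 10,
    clickstream_paths = character(0),
    target_pages = c("Sepsis", "Septic_shock"),
    category_map = NULL,
    fallback_category = "Uncategorized",
    out_dir = "viewspike-output",
    seed = 1L,
    simulate = list()            # overrides for panel_spec()
  )
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  config <- defaults
  config[names(x)] <- x  # wholesale replacement; no recursive merging
  config$params <- do.call(shesd_params, config$shesd)
  structure(config, class = "run_config")
}

validate_inputs <- function(paths, what) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Missing ", what, " file(s): ", paste(missing, collapse = ", ")))
  }
  invisible(paths)
}

write_manifest <- function(config, stage) {
  manifest <- list(
    stage = stage,
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package = as.character(utils::packageVersion("viewspike"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the detection stage
#'
#' Reads the configured Langviews exports, aggregates them to a univariate
#' daily total, runs S-H-ESD detection and the Breusch-Pagan residual
#' diagnostic, and writes the daily total, outlier report, decomposition,
#' diagnostics, and a run manifest under `out_dir`. Inputs are validated
#' before any output is written.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a list with the `shesd` fit, the language share table,
#'   the Breusch-Pagan result, and the written paths.
#' @export
run_detect <- function(config) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config)[
    setdiff(names(config), "params")] else config)
  if (length(config$langviews) == 0) {
    abort("Config field `langviews` must list at least one input file.")
  }
  paths <- vapply(config$langviews, `[[`, character(1), "path")
  validate_inputs(paths, "Langviews")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  panels <- purrr::map(config$langviews, function(lv) {
    read_langviews(lv$path, lv$page %||% "page")
  })
  series <- aggregate_daily_total(panels, zero_fill = config$zero_fill)
  shares <- language_shares(panels, top_k = config$top_k_languages)
  fit <- shesd_detect(series, config$params)
  dec <- fit$decomposition
  bp <- breusch_pagan(dec$remainder, dec$seasonal + dec$trend)

  out <- function(f) file.path(config$out_dir, f)
  write_daily_total(series, out("daily_total.csv"))
  readr::write_csv(dplyr::mutate(tidy(fit), date = format(.data$date)),
                   out("outliers.csv"))
  readr::write_csv(dplyr::mutate(tibble::as_tibble(dec), date = format(.data$date)),
                   out("decomposition.csv"))
  readr::write_csv(shares, out("language_shares.csv"))
  jsonlite::write_json(
    list(n = nrow(series), n_outliers = nrow(fit$outliers),
         breusch_pagan = as.list(bp)),
    out("diagnostics.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(config, "detect")
  inform(paste0("detect: n = ", nrow(series), ", flagged = ",
                nrow(fit$outliers), ", BP p = ", signif(bp$p_value, 3)))
  invisible(list(fit = fit, shares = shares, bp = bp,
                 paths = vapply(c("daily_total.csv", "outliers.csv",
                                  "decomposition.csv", "language_shares.csv",
                                  "diagnostics.json"), out, character(1))))
}

#' Run the epoch-aggregation stage
#'
#' Merges flagged days (from an in-memory fit or the detection stage's
#' `outliers.csv`/`daily_total.csv`) into ranked epochs and writes the
#' media-correlate review table.
#'
#' @param config A [run_config()].
#' @param fit Optional `shesd` fit from [run_detect()]; when `NULL` the
#'   detection artifacts are read from `out_dir`.
#' @return Invisibly, the epoch report tibble.
#' @export
run_epochs <- function(config, fit = NULL) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config)[
    setdiff(names(config), "params")] else config)
  if (is.null(fit)) {
    validate_inputs(file.path(config$out_dir,
                              c("outliers.csv", "daily_total.csv")),
                    "detection-stage")
    outliers <- readr::read_csv(file.path(config$out_dir, "outliers.csv"),
                                show_col_types = FALSE)
    series <- read_daily_total(file.path(config$out_dir, "daily_total.csv"))
  } else {
    outliers <- tidy(fit)
    series <- fit$series
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  epochs <- build_epochs(as.Date(outliers$date), series)
  report <- epoch_report(epochs, file.path(config$out_dir, "epochs.csv"))
  jsonlite::write_json(
    purrr::pmap(epochs, function(epoch, start, end, ...) {
      list(epoch = epoch,
           member_dates = format(seq(start, end, by = "day")))
    }),
    file.path(config$out_dir, "epochs.json"), auto_unbox = TRUE, digits = NA
  )
  write_manifest(config, "epochs")
  inform(paste0("epochs: ", nrow(epochs), " epoch(s) from ",
                nrow(outliers), " flagged day(s)"))
  invisible(report)
}

#' Run the clickstream stage
#'
#' Reads the configured monthly dumps, merges them, categorizes inbound
#' referrers, ranks outbound pages, and writes category totals, the unmapped
#' referrer report, and a conservation-checked Sankey JSON.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with merged edges, category totals, top-k
#'   outbound pages, and the `flow_graph`.
#' @export
run_clickstream <- function(config) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config)[
    setdiff(names(config), "params")] else config)
  if (length(config$clickstream_paths) == 0) {
    abort("Config field `clickstream_paths` must list at least one dump.")
  }
  validate_inputs(config$clickstream_paths, "clickstream")
  cmap <- NULL
  if (!is.null(config$category_map)) {
    validate_inputs(config$category_map, "category-map")
    cmap <- read_category_map(config$category_map)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- merge_months(purrr::map(config$clickstream_paths, read_clickstream,
                                   target_pages = config$target_pages))
  categorized <- categorize_edges(edges, cmap,
                                  fallback = config$fallback_category)
  topk <- topk_outbound(edges, k = config$top_k_outbound)
  target_label <- paste(normalize_title(config$target_pages), collapse = " / ")
  graph <- sankey_export(categorized, topk, target_label,
                         path = file.path(config$out_dir, "sankey.json"))
  readr::write_csv(categorized, file.path(config$out_dir, "category_totals.csv"))
  readr::write_csv(attr(categorized, "unmapped"),
                   file.path(config$out_dir, "unmapped_referrers.csv"))
  write_manifest(config, "clickstream")
  inform(paste0("clickstream: ", nrow(edges), " merged edge(s), inbound total ",
                sum(categorized$n)))
  invisible(list(edges = edges, categorized = categorized, topk = topk,
                 graph = graph))
}

#' Run the simulation stage
#'
#' Generates a synthetic pageview panel and clickstream with the configured
#' seed, writing the same Langviews-style CSV and clickstream TSV the readers
#' consume plus JSON truth files, so the full pipeline can be exercised
#' without downloads.
#'
#' @param config A [run_config()]; `config$simulate` fields are forwarded to
#'   [panel_spec()].
#' @return Invisibly, a list with the generated panel/clickstream objects and
#'   written paths.
#' @export
run_simulate <- function(config) {
  config <- run_config(if (inherits(config, "run_config")) unclass(config)[
    setdiff(names(config), "params")] else config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(panel_spec, config$simulate)
  sim <- gen_pageview_panel(spec, seed = config$seed)
  cs <- gen_clickstream(
    proportions = c("Search engines" = 0.55, "Unknown/refererless" = 0.20,
                    "People" = 0.12, "Conditions" = 0.08,
                    "Medical topics" = 0.05),
    n_events = 100000, target_page = config$target_pages[1],
    seed = config$seed
  )
  out <- function(f) file.path(config$out_dir, f)
  write_langviews(sim$panel, out("synthetic_langviews.csv"))
  jsonlite::write_json(
    list(anomalies = dplyr::mutate(sim$truth$anomalies,
                                   date = format(.data$date)),
         anomaly_dates = format(sim$truth$anomaly_dates),
         noise_sd = sim$truth$noise_sd, seed = config$seed),
    out("synthetic_truth.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_clickstream(cs$edges, out("synthetic_clickstream.tsv"))
  readr::write_csv(cs$category_map, out("synthetic_category_map.csv"))
  jsonlite::write_json(as.list(cs$truth), out("synthetic_clickstream_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(config, "simulate")
  inform(paste0("simulate: ", nrow(sim$panel), " panel record(s), ",
                nrow(cs$edges), " clickstream edge(s)"))
  invisible(list(panel = sim, clickstream = cs,
                 paths = vapply(c("synthetic_langviews.csv",
                                  "synthetic_truth.json",
                                  "synthetic_clickstream.tsv",
                                  "synthetic_category_map.csv",
                                  "synthetic_clickstream_truth.json"),
                                out, character(1))))
}
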