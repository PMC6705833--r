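#' Reserved clickstream referrer tokens and their display categories
#'
#' The monthly dumps aggregate unattributable referrers into reserved tokens;
#' these map to fixed display categories (refererless traffic largely arises
#' from clients on HTTPS whose referrer is stripped).
#'
#' @return A named character vector: token -> category label.
#' @export
reserved_referrer_categories <- function() {
  c("other-search" = "Search engines",
    "other-external" = "Other external",
    "other-empty" = "Unknown/refererless",
    "other-internal" = "Other Wikimedia",
    "other-other" = "Other")
}

# Dumps use underscores, human-curated maps use spaces; match on a common form.
normalize_title <- function(x) {
  gsub("_", " ", stringr::str_trim(x), fixed = TRUE)
}

#' Read a Wikimedia clickstream dump for target pages
#'
#' Parses a tab-separated (prev, curr, type, n) dump, keeping edges whose
#' resource (`curr`) is a target page (inbound) or whose referrer (`prev`)
#' is one (outbound). Title matching is underscore/space-insensitive but
#' otherwise case-sensitive. Malformed rows (wrong field count or
#' non-integer count) are skipped and counted in a message.
#'
#' @param path Path to a clickstream TSV (with or without a header row).
#' @param target_pages Character vector of page titles of interest.
#' @return A tibble with columns `prev`, `curr`, `type`, `n`, `direction`
#'   (`"inbound"`/`"outbound"`). Zero matching edges triggers a warning.
#' @export
read_clickstream <- function(path, target_pages) {
  if (!file.exists(path)) abort(paste0("Input file '", path, "' does not exist."))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0) {
    first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(first) >= 4 && is.na(suppressWarnings(as.integer(first[4])))) {
      lines <- lines[-1]  # header row
    }
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok_shape <- lengths(fields) >= 4
  counts <- suppressWarnings(
    as.numeric(vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_,
                      character(1)))
  )
  ok <- ok_shape & !is.na(counts) & counts == floor(counts) & counts >= 1
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    inform(paste0("Skipped ", n_bad, " malformed clickstream row(s) in '",
                  path, "'."))
  }
  fields <- fields[ok]
  edges <- tibble::tibble(
    prev = vapply(fields, `[`, character(1), 1),
    curr = vapply(fields, `[`, character(1), 2),
    type = vapply(fields, `[`, character(1), 3),
    n = counts[ok]
  )
  targets <- normalize_title(target_pages)
  edges <- edges |>
    dplyr::mutate(
      inbound = normalize_title(.data$curr) %in% targets,
      outbound = normalize_title(.data$prev) %in% targets
    ) |>
    dplyr::filter(.data$inbound | .data$outbound) |>
    dplyr::mutate(direction = ifelse(.data$inbound, "inbound", "outbound")) |>
    dplyr::select("prev", "curr", "type", "n", "direction")
  if (nrow(edges) == 0) {
    warn(paste0("No clickstream edges in '", path, "' match the target pages."))
  }
  edges
}

#' Merge monthly clickstream edge sets
#'
#' Sums counts over identical (prev, curr, type) keys across months; the
#' operation is associative and commutative, so merge order is immaterial.
#'
#' @param edge_sets A list of edge tibbles from [read_clickstream()] (a single
#'   tibble is also accepted).
#' @return One edge tibble with summed counts.
#' @export
merge_months <- function(edge_sets) {
  if (is.data.frame(edge_sets)) edge_sets <- list(edge_sets)
  if (!is.list(edge_sets) || length(edge_sets) == 0) {
    abort("`edge_sets` must be a nonempty list of edge tibbles.")
  }
  keys <- c("prev", "curr", "type",
            if ("direction" %in% names(edge_sets[[1]])) "direction")
  purrr::list_rbind(purrr::map(edge_sets, tibble::as_tibble)) |>
    dplyr::summarise(n = sum(.data$n), .by = dplyr::all_of(keys)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$prev, .data$curr)
}

#' Read a page-category mapping table
#'
#' @param path CSV/TSV with a title column and a category column.
#' @return A tibble with columns `title`, `category`.
#' @export
read_category_map <- function(path) {
  raw <- read_delim_chr(path)
  if (ncol(raw) < 2) abort(paste0("'", path, "' needs (title, category) columns."))
  lowered <- tolower(names(raw))
  t_col <- which(lowered %in% c("title", "page", "prev", "referrer"))
  c_col <- which(lowered %in% c("category", "label", "group"))
  tibble::tibble(
    title = raw[[if (length(t_col) >= 1) t_col[1] else 1L]],
    category = raw[[if (length(c_col) >= 1) c_col[1] else 2L]]
  )
}

#' Categorize inbound clickstream referrers
#'
#' Sums inbound counts per referrer category. Reserved aggregate tokens get
#' their fixed display categories ([reserved_referrer_categories()]); page
#' titles are looked up in `category_map` (underscore/space-insensitive);
#' anything unmapped falls into `fallback` and is reported via the
#' `unmapped` attribute. The category grand total equals the raw inbound
#' grand total exactly.
#'
#' @param edges An edge tibble (only rows with `direction == "inbound"` are
#'   used when that column is present).
#' @param category_map A tibble (`title`, `category`) or named character
#'   vector; may be empty.
#' @param fallback Category label for unmapped titles.
#' @return A tibble (`category`, `n`) sorted by descending count, with
#'   attribute `unmapped`: a tibble of unmapped titles and their counts.
#' @export
categorize_edges <- function(edges, category_map = NULL,
                             fallback = "Uncategorized") {
  edges <- tibble::as_tibble(edges)
  if ("direction" %in% names(edges)) {
    edges <- dplyr::filter(edges, .data$direction == "inbound")
  }
  if (is.null(category_map)) {
    category_map <- tibble::tibble(title = character(0), category = character(0))
  }
  if (!is.data.frame(category_map)) {
    category_map <- tibble::tibble(title = names(category_map),
                                   category = unname(category_map))
  }
  reserved <- reserved_referrer_categories()
  lookup <- setNames(category_map$category, normalize_title(category_map$title))
  key <- normalize_title(edges$prev)
  cat <- unname(lookup[key])
  is_reserved <- edges$prev %in% names(reserved)
  cat[is_reserved] <- reserved[edges$prev[is_reserved]]
  unmapped_mask <- is.na(cat)
  cat[unmapped_mask] <- fallback
  unmapped <- edges[unmapped_mask, ] |>
    dplyr::summarise(n = sum(.data$n), .by = "prev") |>
    dplyr::arrange(dplyr::desc(.data$n))
  out <- tibble::tibble(category = cat, n = edges$n) |>
    dplyr::summarise(n = sum(.data$n), .by = "category") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$category)
  attr(out, "unmapped") <- unmapped
  out
}

#' Top-k outbound pages
#'
#' Ranks internal (`type == "link"`) outbound referrals by count, ties broken
#' by title, and returns the top `k` (all, if fewer exist). Only link-type
#' edges count as internal Wikipedia referrals.
#'
#' @param edges An edge tibble (rows with `direction == "outbound"` are used
#'   when that column is present).
#' @param k Number of pages to keep.
#' @return A tibble (`page`, `n`), at most `k` rows.
#' @export
topk_outbound <- function(edges, k = 10) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) abort("`k` must be >= 1.")
  edges <- tibble::as_tibble(edges)
  if ("direction" %in% names(edges)) {
    edges <- dplyr::filter(edges, .data$direction == "outbound")
  }
  edges |>
    dplyr::filter(.data$type == "link") |>
    dplyr::summarise(n = sum(.data$n), .by = "curr") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$curr) |>
    dplyr::rename(page = "curr") |>
    head(k)
}

#' Export a Sankey flow document
#'
#' Builds a nodes/links flow graph: inbound referrer categories on the left,
#' the target page in the middle, top-k outbound pages on the right. Link
#' `source`/`target` are 0-based node indices, as common Sankey renderers
#' expect. The inbound side is conservation-checked: the summed link weights
#' must equal the categorized totals exactly (an internal bug guard).
#'
#' @param categorized Category totals from [categorize_edges()].
#' @param topk Outbound top-k table from [topk_outbound()] (may have 0 rows).
#' @param target_label Display label of the target page(s).
#' @param path Optional JSON output path.
#' @return A list of class `flow_graph` with `nodes` (tibble: `name`) and
#'   `links` (tibble: `source`, `target`, `value`).
#' @export
sankey_export <- function(categorized, topk = NULL, target_label, path = NULL) {
  if (nrow(categorized) == 0) abort("Inbound category totals are empty.")
  if (is.null(topk)) topk <- tibble::tibble(page = character(0), n = numeric(0))
  nodes <- tibble::tibble(name = c(categorized$category, target_label, topk$page))
  target_idx <- nrow(categorized)  # 0-based position of the target node
  links <- dplyr::bind_rows(
    tibble::tibble(source = seq_len(nrow(categorized)) - 1L,
                   target = target_idx, value = categorized$n),
    tibble::tibble(source = target_idx,
                   target = target_idx + seq_len(nrow(topk)),
                   value = topk$n)
  )
  inbound_sum <- sum(links$value[links$target == target_idx])
  if (inbound_sum != sum(categorized$n)) {
    abort("Internal error: Sankey inbound weights violate conservation.")
  }
  if (any(links$value < 1)) {
    abort("Internal error: Sankey link weights must be >= 1.")
  }
  graph <- structure(list(nodes = nodes, links = links), class = "flow_graph")
  if (!is.null(path)) {
    jsonlite::write_json(
      list(nodes = purrr::map(nodes$name, ~list(name = .x)),
           links = purrr::pmap(links, function(source, target, value) {
             list(source = source, target = target, value = value)
           })),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  graph
}

#' Write clickstream edges as a dump-style TSV
#'
#' @param edges Edge tibble (`prev`, `curr`, `type`, `n`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clickstream <- function(edges, path) {
  readr::write_tsv(edges[c("prev", "curr", "type", "n")], path,
                   col_names = FALSE)
  invisible(path)
}
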