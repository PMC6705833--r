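cs_lines <- c(
  "other-search\tSepsis\texternal\t500",
  "Bacteremia\tSepsis\tlink\t20",
  "Muhammad_Ali\tSepsis\tlink\t400",
  "Sepsis\tSeptic_shock\tlink\t77",
  "Sepsis\tGangrene\tlink\t33",
  "Unrelated\tOther_page\tlink\t9"
)

test_that("clickstream dumps parse with target filtering and malformed-row skipping", {
  f <- write_tmp(cs_lines, ext = ".tsv")
  edges <- read_clickstream(f, c("Sepsis"))
  expect_equal(nrow(edges), 5)  # the Unrelated -> Other_page row is dropped
  inbound <- dplyr::filter(edges, direction == "inbound")
  expect_equal(sum(inbound$n), 920)
  expect_equal(sum(edges$n[edges$direction == "outbound"]), 110)

  g <- write_tmp(c(cs_lines, "Broken\tSepsis\tlink\tnot_a_number",
                   "too\tfew"), ext = ".tsv")
  expect_message(edges2 <- read_clickstream(g, "Sepsis"), "2 malformed")
  expect_equal(sum(edges2$n), sum(edges$n))

  h <- write_tmp(c("prev\tcurr\ttype\tn", cs_lines), ext = ".tsv")
  expect_equal(nrow(read_clickstream(h, "Sepsis")), 5)  # header detected

  expect_warning(read_clickstream(write_tmp("a\tb\tlink\t5", ext = ".tsv"),
                                  "Sepsis"), "No clickstream edges")
})

test_that("title matching is underscore/space-insensitive but case-sensitive", {
  f <- write_tmp(c("Septic_shock\tGangrene\tlink\t5",
                   "septic_shock\tGangrene\tlink\t4"), ext = ".tsv")
  edges <- read_clickstream(f, "Septic shock")  # space form matches underscores
  expect_equal(edges$direction, "outbound")     # lowercase variant not matched
  expect_equal(edges$prev, "Septic_shock")
})

test_that("merging months sums identical keys and matches the brute-force oracle", {
  a <- tibble::tibble(prev = "other-search", curr = "Sepsis",
                      type = "external", n = 10, direction = "inbound")
  b <- dplyr::mutate(a, n = 15)
  merged <- merge_months(list(a, b))
  expect_equal(merged$n, 25)

  disjoint <- tibble::tibble(prev = "X", curr = "Sepsis", type = "link",
                             n = 3, direction = "inbound")
  expect_equal(nrow(merge_months(list(a, disjoint))), 2)

  set.seed(23)
  mk_month <- function() tibble::tibble(
    prev = sample(letters[1:5], 20, replace = TRUE),
    curr = "Sepsis", type = sample(c("link", "external"), 20, replace = TRUE),
    n = sample(1:50, 20, replace = TRUE), direction = "inbound"
  )
  months <- list(mk_month(), mk_month(), mk_month())
  merged <- merge_months(months)
  all_rows <- do.call(rbind, months)
  for (i in seq_len(nrow(merged))) {
    hit <- all_rows$prev == merged$prev[i] & all_rows$type == merged$type[i]
    expect_equal(merged$n[i], sum(all_rows$n[hit]))
  }
  # associative and commutative
  expect_equal(
    dplyr::arrange(merge_months(list(merge_months(months[1:2]), months[[3]])),
                   prev, type),
    dplyr::arrange(merge_months(rev(months)), prev, type)
  )
})

test_that("categorization conserves counts and reports unmapped titles", {
  f <- write_tmp(cs_lines, ext = ".tsv")
  edges <- read_clickstream(f, "Sepsis")
  cmap <- tibble::tibble(title = c("Bacteremia", "Muhammad Ali"),
                         category = c("Conditions", "People"))
  cats <- categorize_edges(edges, cmap)
  expect_equal(cats$n[cats$category == "Search engines"], 500)
  expect_equal(cats$n[cats$category == "People"], 400)
  expect_equal(cats$n[cats$category == "Conditions"], 20)
  expect_identical(sum(cats$n), sum(edges$n[edges$direction == "inbound"]))
  expect_equal(nrow(attr(cats, "unmapped")), 0)

  # empty map: all non-reserved inbound mass falls into the fallback
  bare <- categorize_edges(edges, NULL, fallback = "Uncategorized")
  expect_equal(bare$n[bare$category == "Uncategorized"], 420)
  expect_identical(sum(bare$n), 920)
  expect_setequal(attr(bare, "unmapped")$prev, c("Bacteremia", "Muhammad_Ali"))

  # determinism: the same map applied twice changes nothing
  expect_identical(cats, categorize_edges(edges, cmap))
})

test_that("top-k outbound ranks link-type edges with lexicographic tie-breaks", {
  edges <- tibble::tibble(
    prev = "Sepsis",
    curr = c("B", "A", "C", "D"),
    type = c("link", "link", "link", "external"),
    n = c(30, 30, 10, 99),
    direction = "outbound"
  )
  top2 <- topk_outbound(edges, 2)
  expect_equal(top2$page, c("A", "B"))  # tie at 30 broken by title
  expect_equal(nrow(topk_outbound(edges, 10)), 3)  # clamps; external excluded
  expect_error(topk_outbound(edges, 0), "k")

  set.seed(37)
  big <- tibble::tibble(prev = "Sepsis", curr = paste0("p", 1:50),
                        type = "link", n = sample(1:1000, 50),
                        direction = "outbound")
  expect_equal(topk_outbound(big, 7)$page,
               big$curr[order(-big$n, big$curr)][1:7])
})

test_that("Sankey export is conservation-checked and schema-shaped", {
  f <- write_tmp(cs_lines, ext = ".tsv")
  edges <- read_clickstream(f, "Sepsis")
  cmap <- tibble::tibble(title = c("Bacteremia", "Muhammad Ali"),
                         category = c("Conditions", "People"))
  cats <- categorize_edges(edges, cmap)
  topk <- topk_outbound(edges, 10)
  out <- withr::local_tempfile(fileext = ".json")
  graph <- sankey_export(cats, topk, "Sepsis", path = out)
  inbound_links <- graph$links[graph$links$target == nrow(cats), ]
  expect_equal(sum(inbound_links$value), 920)
  expect_true(all(graph$links$value >= 1))
  doc <- jsonlite::read_json(out)
  expect_named(doc, c("nodes", "links"))
  expect_true(all(vapply(doc$links, function(l) l$value >= 1, logical(1))))
  expect_equal(length(doc$nodes), nrow(cats) + 1 + nrow(topk))
  expect_error(sankey_export(cats[0, ], topk, "Sepsis"), "empty")
})

test_that("generated clickstreams re-read to identical totals and match truth", {
  props <- c("Search engines" = 0.5, "People" = 0.3, "Conditions" = 0.2)
  cs <- gen_clickstream(props, n_events = 20000, seed = 19)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clickstream(cs$edges, f)
  back <- read_clickstream(f, "Sepsis")
  expect_equal(sum(back$n), sum(cs$edges$n))
  cats <- categorize_edges(back, cs$category_map)
  truth <- cs$truth$category_totals
  for (i in seq_len(nrow(truth))) {
    expect_equal(cats$n[cats$category == truth$category[i]], truth$n[i])
  }
  expect_identical(sum(cats$n), sum(back$n[back$direction == "inbound"]))
})
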