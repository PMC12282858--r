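# Per-cell visuals: colors, geometry, pills, ellipsis, linkouts, notation,
# histograms.

linear_scale <- function(domain = c(0, 1), colors = c("#ffffff", "#ff0000"),
                         clamp = TRUE) {
  list(kind = "linear", domain = domain, colors = colors, clamp = clamp)
}

test_that("linear heatmaps interpolate per RGB channel with half-up rounding", {
  s <- linear_scale()
  expect_equal(heatmap_color(0, s), "#ffffff")
  expect_equal(heatmap_color(1, s), "#ff0000")
  expect_equal(heatmap_color(0.5, s), "#ff8080")   # 127.5 rounds half-up to 128
  expect_equal(heatmap_color(1.7, s), "#ff0000")   # clamped
  expect_equal(heatmap_color(-3, s), "#ffffff")
  # multi-anchor scale: value at an interior anchor hits it exactly
  s3 <- linear_scale(domain = c(0, 10),
                     colors = c("#000000", "#808080", "#ffffff"))
  expect_equal(heatmap_color(5, s3), "#808080")
  expect_equal(heatmap_color(10, s3), "#ffffff")
})

test_that("heatmap channels are monotone within one anchor segment", {
  s <- linear_scale(domain = c(0, 1), colors = c("#102030", "#c0d0e0"))
  values <- seq(0, 1, by = 0.05)
  reds <- vapply(values, function(v) {
    strtoi(substr(heatmap_color(v, s), 2, 3), 16L)
  }, integer(1))
  expect_true(!is.unsorted(reds))
})

test_that("categorical scales look up exactly and fall back to white", {
  s <- list(kind = "categorical", domain = c("G", "PG"),
            colors = list(G = "#2CA02C", PG = "#ff7f0e"))
  expect_equal(heatmap_color("G", s), "#2ca02c")
  expect_warning(fallback <- heatmap_color("R", s),
                 class = "tabreport_scale_warning")
  expect_equal(fallback, "#ffffff")
})

test_that("tick fractions clamp into the unit interval", {
  expect_equal(tick_fraction(5, c(0, 10)), 0.5)
  expect_equal(tick_fraction(0, c(0, 10)), 0)
  expect_equal(tick_fraction(12, c(0, 10)), 1)
  expect_warning(na_frac <- tick_fraction("text", c(0, 10)),
                 class = "tabreport_render_warning")
  expect_true(is.na(na_frac))
})

test_that("bar geometry combines the tick fraction with the color scale", {
  spec_plain <- list(domain = c(0, 100), color_scale = NULL)
  g <- bar_geometry(25, spec_plain)
  expect_equal(g$fraction, 0.25)
  expect_equal(g$fill, "#4682b4")
  spec_col <- list(domain = c(0, 100),
                   color_scale = linear_scale(c(0, 100)))
  expect_equal(bar_geometry(100, spec_col)$fill, "#ff0000")
  # agreement with independent recomputation on random values
  set.seed(5)
  for (v in stats::runif(20, -20, 120)) {
    g <- bar_geometry(v, spec_col)
    expect_equal(g$fraction, min(1, max(0, v / 100)))
    expect_equal(g$fill, heatmap_color(v, spec_col$color_scale))
  }
})

test_that("pills split, trim, count and preserve first-occurrence order", {
  p <- split_pills("A;B;A", ";")
  expect_equal(p$value, c("A", "B"))
  expect_equal(p$count, c(2L, 1L))
  expect_equal(nrow(split_pills("", ";")), 0L)
  trimmed <- split_pills(" x , y ,x", ",")
  expect_equal(trimmed$value, c("x", "y"))
  expect_equal(trimmed$count, c(2L, 1L))
  # counts conserve the number of non-empty tokens
  expect_equal(sum(split_pills("a;;b; ;a;c", ";")$count), 4L)
})

test_that("ellipsis truncation keeps the full text for the tooltip", {
  t1 <- truncate_ellipsis("abcdefgh", 5)
  expect_equal(t1$shown, "abcde…")
  expect_equal(t1$full, "abcdefgh")
  expect_true(t1$truncated)
  expect_equal(truncate_ellipsis("abc", 8),
               list(shown = "abc", full = "abc", truncated = FALSE))
  expect_false(truncate_ellipsis("abc", 3)$truncated)
})

test_that("linkout templates substitute encoded values from cell and row", {
  row <- list(gene = "TP53", id = "x 1")
  expect_equal(
    format_linkout("https://www.ncbi.nlm.nih.gov/gene/?term={value}",
                   row, "TP53"),
    "https://www.ncbi.nlm.nih.gov/gene/?term=TP53")
  expect_equal(format_linkout("https://x.org/{value}", row, "foo bar"),
               "https://x.org/foo%20bar")
  expect_equal(format_linkout("https://x.org/{gene}/{id}", row, "ignored"),
               "https://x.org/TP53/x%201")
  expect_error(format_linkout("https://x.org/{ghost}", row, "v"),
               "ghost")
})

test_that("scientific notation keeps 3 significant digits and thresholds", {
  expect_equal(sci_notation(0.000032), "3.20e-5")
  expect_equal(sci_notation(0), "0")
  expect_equal(sci_notation(1234, format = "auto"), "1234")
  expect_equal(sci_notation(0.0005, format = "auto"), "5.00e-4")
  expect_equal(sci_notation(2.5e7, format = "auto"), "2.50e+7")
  expect_equal(sci_notation(0.25, format = "scientific"), "2.50e-1")
  expect_equal(sci_notation(9.999e5, format = "auto"), "999900")
})

test_that("histograms bin numerics into 10 equal widths and count nominals", {
  h <- column_histogram(0:9)
  expect_equal(nrow(h), 10L)
  expect_equal(h$count, rep(1L, 10))
  expect_equal(h$lo[1], 0)
  expect_equal(h$hi[10], 9)
  const <- column_histogram(c(5, 5, 5))
  expect_equal(nrow(const), 1L)
  expect_equal(const$count, 3L)
  nom <- column_histogram(c("b", "a", "a", "c", "b", "a"))
  expect_equal(nom$value, c("a", "b", "c"))
  expect_equal(nom$count, c(3L, 2L, 1L))
  # conservation on random data
  for (seed in 1:8) {
    set.seed(seed)
    x <- c(stats::rnorm(50), rep(NA, 5))
    expect_equal(sum(column_histogram(x)$count), 50L)
    s <- sample(c(letters[1:20], NA), 100, replace = TRUE)
    h2 <- column_histogram(s)
    expect_lte(nrow(h2), 15L)   # top-15 truncation
    expect_equal(attr(h2, "n"), sum(!is.na(s)))
  }
})

test_that("autoplot produces ggplot objects for both histogram kinds", {
  expect_s3_class(ggplot2::autoplot(column_histogram(stats::rnorm(30))),
                  "ggplot")
  expect_s3_class(ggplot2::autoplot(column_histogram(letters[1:10])),
                  "ggplot")
  expect_s3_class(ggplot2::autoplot(compression_report(tiny_table())),
                  "ggplot")
})
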