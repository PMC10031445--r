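# Wheel and detail-panel rendering, verified by parsing the emitted SVG.

library(xml2)

parse_svg <- function(svg) xml_ns_strip(read_xml(svg))

layout_colors <- default_wheel_layout(ref_cfg)$colors

test_that("the wheel has 4 equal quadrants and one icon per parameter", {
  p <- build_profile(demo_assessment(), ref_cfg)
  doc <- parse_svg(render_wheel(p, ref_cfg))
  quads <- xml_find_all(doc, "//g[@class='quadrant']")
  expect_length(quads, 4L)
  spans <- as.numeric(xml_attr(quads, "data-span"))
  expect_true(all(spans == 90))
  expect_identical(sum(spans), 360)
  icons <- xml_find_all(doc, "//g[@class='param-icon']")
  expect_length(icons, 21L)
  # stable identifiers enabling click-through linkage
  expect_setequal(xml_attr(icons, "id"),
                  paste0("icon-", ref_cfg$parameter_order))
  expect_true(all(xml_attr(icons, "data-detail") ==
                    paste0("detail-", sub("^icon-", "", xml_attr(icons, "id")), ".svg")))
})

test_that("icon fill colors form a bijection with parameter statuses", {
  p <- build_profile(demo_assessment(), ref_cfg)
  doc <- parse_svg(render_wheel(p, ref_cfg))
  for (icon in xml_find_all(doc, "//g[@class='param-icon']")) {
    pid <- sub("^icon-", "", xml_attr(icon, "id"))
    fill <- xml_attr(xml_find_first(icon, "./circle"), "fill")
    expect_identical(fill, layout_colors[[p$parameter_status[[pid]]]], info = pid)
    expect_identical(xml_attr(icon, "data-status"), p$parameter_status[[pid]])
  }
  expect_true(all(vapply(layout_colors, nchar, 0L) == 7L)) # 4 configured colors
})

test_that("a fully unanswered profile renders all icons gray", {
  empty <- new_assessment("ghost", "2026-01-01")
  p <- build_profile(empty, ref_cfg)
  expect_true(all(unlist(p$parameter_status) == "gray"))
  doc <- parse_svg(render_wheel(p, ref_cfg))
  fills <- xml_attr(xml_find_all(doc, "//g[@class='param-icon']/circle"), "fill")
  expect_true(all(fills == layout_colors$gray))
})

test_that("more than 6 parameters in a quadrant is an error, never truncation", {
  p <- build_profile(healthy_assessment(), ref_cfg)
  crowded <- ref_cfg
  crowded$domains$behavior$parameter_ids <-
    c(crowded$domains$behavior$parameter_ids, list("weight"))
  expect_error(render_wheel(p, crowded), "at most 6")
})

test_that("rendered text uses the config's lay labels, not technical terms", {
  p <- build_profile(demo_assessment(), ref_cfg)
  # label table: every parameter label in the SVG equals cfg's lay label
  expect_identical(ref_cfg$parameters$glucose_metabolism$label_lay, "Blood sugar")
  svg <- render_detail(p, "glucose_metabolism", ref_cfg)
  doc <- parse_svg(svg)
  title <- xml_text(xml_find_first(doc, "//text"))
  expect_identical(title, "Blood sugar")
})

test_that("detail panels draw one band bar per element with markers in place", {
  p <- build_profile(demo_assessment(), ref_cfg)
  doc <- parse_svg(render_detail(p, "blood_pressure", ref_cfg))
  bars <- xml_find_all(doc, "//g[@class='element-bar']")
  expect_length(bars, 2L)
  # (150, 95): each marker must sit inside its orange segment
  for (info in list(list(id = "element-systolic", value = 150),
                    list(id = "element-diastolic", value = 95))) {
    bar <- xml_find_first(doc, sprintf("//g[@id='%s']", info$id))
    seg <- xml_find_first(bar, "./rect[@class='band-orange']")
    x0 <- as.numeric(xml_attr(seg, "x"))
    x1 <- x0 + as.numeric(xml_attr(seg, "width"))
    marker <- xml_find_first(bar, "./path[@class='score-marker']")
    mx <- as.numeric(strsplit(xml_attr(marker, "d"), " ")[[1]][[2]]) + 6
    expect_gte(mx, x0); expect_lte(mx, x1)
    label <- xml_text(xml_find_first(bar, "./text[@class='score-label']"))
    expect_identical(label, as.character(info$value))
  }
  # single-element parameter: one bar
  doc1 <- parse_svg(render_detail(p, "perceived_stress", ref_cfg))
  expect_length(xml_find_all(doc1, "//g[@class='element-bar']"), 1L)
  expect_error(render_detail(p, "aura", ref_cfg), "unknown parameter")
})

test_that("missing elements render without marker and with an annotation", {
  a <- healthy_assessment()
  a$item_responses$who5 <- rep(NA, 5)
  p <- build_profile(a, ref_cfg)
  doc <- parse_svg(render_detail(p, "mental_health", ref_cfg))
  bar <- xml_find_first(doc, "//g[@id='element-who5_score']")
  expect_length(xml_find_all(bar, "./path[@class='score-marker']"), 0L)
  expect_length(xml_find_all(bar, "./text[@class='not-answered']"), 1L)
  # the bar itself still shows the cutoff segments (two-color scale)
  expect_length(xml_find_all(bar, "./rect"), 2L)
})

test_that("rendering is deterministic: byte-identical across runs", {
  p <- build_profile(demo_assessment(), ref_cfg)
  expect_identical(render_wheel(p, ref_cfg), render_wheel(p, ref_cfg))
  expect_identical(render_detail(p, "weight", ref_cfg),
                   render_detail(p, "weight", ref_cfg))
})
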