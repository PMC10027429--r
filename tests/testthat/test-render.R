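# Ribbon geometry, ticks, glyphs, SVG serialization, PNG backend.

anchors_fixture <- function(edge_a = "bottom", edge_b = "top") {
  structure(list(a_start = c(10, 20), a_end = c(110, 20),
                 b_start = c(40, 120), b_end = c(160, 120),
                 edge_a = edge_a, edge_b = edge_b),
            class = "ribbon_anchors")
}

seg_points <- function(prim) do.call(rbind, lapply(prim$segments, `[[`, "pts"))

test_that("style 1 is a straight quadrilateral through the four anchors", {
  an <- anchors_fixture()
  p <- build_ribbon_path(an, style = 1)
  cmds <- vapply(p$segments, `[[`, "", "cmd")
  expect_equal(cmds, c("M", "L", "L", "L", "Z"))
  pts <- seg_points(p)
  expect_equal(pts[1, ], an$a_start)
  expect_equal(pts[2, ], an$a_end)
  expect_equal(pts[3, ], an$b_end)
  expect_equal(pts[4, ], an$b_start)
})

test_that("curved styles start and end exactly at the anchors", {
  an <- anchors_fixture()
  for (st in 2:5) {
    p <- build_ribbon_path(an, style = st, height_ratio = 1.7, default_height = 90)
    expect_equal(p$segments[[1]]$pts[1, ], an$a_start)
    last_c <- p$segments[[3]]$pts          # C to b_end
    expect_equal(last_c[nrow(last_c), ], an$b_end)
    back_c <- p$segments[[5]]$pts          # C back to a_start
    expect_equal(back_c[nrow(back_c), ], an$a_start)
  }
  expect_error(build_ribbon_path(an, style = 6), "1\\.\\.5")
  expect_error(build_ribbon_path(an, style = 0), "1\\.\\.5")
})

test_that("style-2 curves collapse onto the chord as height_ratio -> 0", {
  an <- anchors_fixture()
  p <- build_ribbon_path(an, style = 2, height_ratio = 1e-8, default_height = 100)
  cseg <- p$segments[[3]]        # a_end -> b_end cubic
  t <- seq(0, 1, length.out = 100)
  curve <- cubic_bezier(t, an$a_end, cseg$pts[1, ], cseg$pts[2, ], cseg$pts[3, ])
  # max perpendicular deviation from the straight chord
  v <- an$b_end - an$a_end
  dev <- abs(v[1] * (curve[, 2] - an$a_end[2]) - v[2] * (curve[, 1] - an$a_end[1])) /
    sqrt(sum(v^2))
  expect_lt(max(dev), 1e-6)
})

test_that("doubling height_ratio doubles control-point offsets (styles 2-5)", {
  an <- anchors_fixture()
  for (st in 2:5) {
    p1 <- build_ribbon_path(an, style = st, height_ratio = 1, default_height = 80)
    p2 <- build_ribbon_path(an, style = st, height_ratio = 2, default_height = 80)
    off1 <- p1$segments[[3]]$pts[1, 2] - an$a_end[2]
    off2 <- p2$segments[[3]]$pts[1, 2] - an$a_end[2]
    expect_equal(off2, 2 * off1)
    expect_true(abs(off1) > 0)
  }
})

test_that("control points stay inside the anchor box expanded by hr*height", {
  set.seed(12)
  for (i in 1:50) {
    an <- anchors_fixture()
    an$a_start <- runif(2, 0, 500); an$a_end <- runif(2, 0, 500)
    an$b_start <- runif(2, 0, 500); an$b_end <- runif(2, 0, 500)
    hr <- runif(1, 0.1, 3); dh <- runif(1, 10, 200)
    st <- sample(2:5, 1)
    p <- build_ribbon_path(an, style = st, height_ratio = hr, default_height = dh)
    pts <- seg_points(p)
    box_x <- range(c(an$a_start[1], an$a_end[1], an$b_start[1], an$b_end[1]))
    box_y <- range(c(an$a_start[2], an$a_end[2], an$b_start[2], an$b_end[2]))
    expect_true(all(pts[, 1] >= box_x[1] - 1e-9 & pts[, 1] <= box_x[2] + 1e-9))
    expect_true(all(pts[, 2] >= box_y[1] - hr * dh - 1e-9 &
                    pts[, 2] <= box_y[2] + hr * dh + 1e-9))
  }
})

test_that("tick spacing follows the 1/2/5 rule (independent oracle)", {
  # oracle: brute-force the largest 1/2/5*10^k step giving 3..8 in-window ticks
  oracle_step <- function(lo, hi) {
    cand <- sort(as.vector(outer(c(1, 2, 5), 10^(0:9))))
    best <- NA
    for (s in cand) {
      n <- floor(hi / s) - ceiling(max(lo, 1) / s) + 1
      if (n >= 3 && n <= 8) best <- s
    }
    best
  }
  cases <- list(c(0, 5964930), c(1, 100), c(1, 1e6), c(5000, 123456),
                c(1, 2.5e8), c(300, 9000))
  for (w in cases) {
    nt <- nice_ticks(w[1], w[2])
    expect_equal(nt$step, oracle_step(w[1], w[2]), info = paste(w, collapse = "-"))
    expect_true(length(nt$positions) >= 3 && length(nt$positions) <= 8)
  }
  # the two worked spacings: ~6 Mb window -> 1 Mb majors (5 ticks);
  # 100 bp window -> 20 bp majors with bp labels
  nt1 <- nice_ticks(0, 5964930)
  expect_equal(nt1$step, 1e6)
  expect_length(nt1$positions, 5L)
  expect_equal(nt1$unit, "Mb")
  nt2 <- nice_ticks(1, 100)
  expect_equal(nt2$step, 20)
  expect_equal(nt2$labels[1], "20 bp")
})

test_that("axis primitives appear only when coordinates are shown", {
  tr <- simple_track(len = 5964930, base_scale = 1e-4)
  r <- tr$rects[1, ]
  expect_length(build_axis_ticks(r, show_coordinates = FALSE), 0L)
  prims <- build_axis_ticks(r, show_coordinates = TRUE)
  expect_length(prims, 2L * 5L)          # line + label per major tick
  kinds <- vapply(prims, `[[`, "", "kind")
  expect_equal(sum(kinds == "line"), 5L)
})

test_that("feature glyphs center on the chromosome and honor the width ratio", {
  tr <- simple_track(len = 1000, base_scale = 1)
  r <- tr$rects[1, ]                      # height 20, y0 0
  p <- default_genome_params()
  feat <- data.frame(seq_id = "c1", start = 100, end = 200)
  feat$attrs <- list(parse_attr_fields("feature=CDS"))

  g1 <- build_feature_glyph(feat, r, p)
  expect_equal(g1$height, 20)            # ratio 1 -> equals chr height
  expect_equal(g1$y, 0)
  p$spe_region_width_ratio <- 1.5
  g2 <- build_feature_glyph(feat, r, p)
  expect_equal(g2$height, 30)
  expect_equal(g2$y, -(30 - 20) / 2)     # overhangs 25% of chr height per edge
  # record fill beats the type default
  feat$attrs <- list(parse_attr_fields(c("feature=CDS", "fill=green")))
  g3 <- build_feature_glyph(feat, r, p)
  expect_equal(g3$fill, "green")
})

test_that("SVG output is well-formed, whitelisted and byte-deterministic", {
  fx <- make_fixture(tempfile("svg"), seed = 2)
  model <- parse_config(fx$config)
  sc <- layout_scene(model)
  svg1 <- render_svg(sc)
  svg2 <- render_svg(layout_scene(parse_config(fx$config)))
  expect_identical(svg1, svg2)

  doc <- xml2::read_xml(svg1)
  expect_equal(xml2::xml_name(doc), "svg")
  tags <- unique(xml2::xml_name(xml2::xml_find_all(doc, "//*")))
  expect_true(all(tags %in% c("svg", "g", "rect", "path", "line", "text")))
  # primitive count oracle: drawable XML elements match scene primitives
  n_prims <- sum(lengths(sc$layers))
  n_drawable <- length(xml2::xml_find_all(doc, "//*[self::*[local-name()='rect' or local-name()='path' or local-name()='line' or local-name()='text']]"))
  expect_equal(n_drawable, n_prims)
})

test_that("an empty scene is still a minimal valid SVG", {
  sc <- structure(list(width = 100, height = 50,
                       layers = list(ribbons = list(), tracks = list(),
                                     features = list(), axes = list(),
                                     labels = list()),
                       tracks = list(), counts = list()),
                  class = "syn_scene")
  svg <- render_svg(sc)
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")
  expect_length(xml2::xml_children(doc), 0L)
})

test_that("duplicate primitive ids are rejected", {
  sc <- structure(list(width = 10, height = 10,
                       layers = list(ribbons = list(), tracks = list(
                         list(kind = "rect", id = "x", x = 0, y = 0, width = 1,
                              height = 1, rx = 0, fill = "red", stroke = "none",
                              transform = NULL),
                         list(kind = "rect", id = "x", x = 2, y = 0, width = 1,
                              height = 1, rx = 0, fill = "red", stroke = "none",
                              transform = NULL)),
                         features = list(), axes = list(), labels = list()),
                       tracks = list(), counts = list()),
                  class = "syn_scene")
  expect_error(render_svg(sc), "duplicate primitive id")
})

test_that("PNG rasterization either works or fails with a clear message", {
  fx <- make_fixture(tempfile("png"), seed = 3, n_genomes = 2)
  svg <- render_svg(layout_scene(parse_config(fx$config)))
  png_path <- tempfile(fileext = ".png")
  if (has_png_backend()) {
    rasterize_png(svg, png_path, dpi = 96)
    expect_true(file.exists(png_path))
    expect_gt(file.info(png_path)$size, 0)
  } else {
    expect_error(rasterize_png(svg, png_path), "backend")
    expect_false(file.exists(png_path))
  }
})
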