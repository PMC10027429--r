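# Track geometry, bp -> canvas mapping, clipping and ribbon anchors.

test_that("chromosomes are laid left to right with spacing (arithmetic oracle)", {
  g <- new_genome_def_test("g", data.frame(seq_id = c("c1", "c2"),
                                           start = c(1, 1), end = c(1000, 500)))
  p <- default_genome_params()
  p$chr_spacing <- 7
  s <- 0.05
  tr <- build_track(g, p, default_slot_y = 0, base_scale = s, default_x = 0)
  w1 <- (1000 - 1) * s
  expect_equal(tr$rects$x0, c(0, w1 + 7))
  expect_equal(tr$rects$x1, c(w1, w1 + 7 + (500 - 1) * s))
  # total baseline width = sum of scaled bp widths + gaps
  expect_equal(max(tr$rects$x1), (1000 - 1) * s + (500 - 1) * s + 7)
})

test_that("identity params give a slot translation; rotation turns the baseline", {
  tr <- simple_track(slot_y = 80)
  T <- tr$transform
  expect_equal(c(T$a, T$b, T$c, T$d, T$e, T$f), c(1, 0, 0, 1, 0, 80))
  # rotate_chr = 90 (counter-clockwise, y down) maps (1,0) -> (0,-1)
  tr90 <- simple_track(params = list(rotate_chr = 90))
  v <- affine_apply(tr90$transform, c(1, 0)) - affine_apply(tr90$transform, c(0, 0))
  expect_equal(v, c(0, -1), tolerance = 1e-12)
})

test_that("bp_to_canvas maps window bounds to rect edges, affinely", {
  tr <- simple_track(len = 1001, base_scale = 0.1)
  r <- tr$rects[1, ]
  expect_equal(bp_to_canvas(tr, "c1", 1, "top"), c(r$x0, 0))
  expect_equal(bp_to_canvas(tr, "c1", 1001, "top"), c(r$x1, 0))
  mid <- bp_to_canvas(tr, "c1", 501, "top")
  expect_equal(mid[1], (r$x0 + r$x1) / 2)
  expect_error(bp_to_canvas(tr, "c1", 2000), "outside")
  expect_error(bp_to_canvas(tr, "nope", 1), "not in track")
})

test_that("zoom_chr=2 doubles canvas distances (numeric comparison)", {
  t1 <- simple_track(params = list(zoom_chr = 1))
  t2 <- simple_track(params = list(zoom_chr = 2))
  p_a1 <- bp_to_canvas(t1, "c1", 100); p_b1 <- bp_to_canvas(t1, "c1", 900)
  p_a2 <- bp_to_canvas(t2, "c1", 100); p_b2 <- bp_to_canvas(t2, "c1", 900)
  d1 <- sqrt(sum((p_b1 - p_a1)^2)); d2 <- sqrt(sum((p_b2 - p_a2)^2))
  expect_equal(d2 / d1, 2, tolerance = 1e-12)
})

test_that("zoom regions reduce the track to the requested slice", {
  g <- new_genome_def_test("g", data.frame(seq_id = c("c1", "c2"),
                                           start = c(1, 1), end = c(1000, 500)))
  p <- default_genome_params()
  p$zoom_region <- parse_region("c2:100:300")
  tr <- build_track(g, p, 0, base_scale = 0.1, default_x = 0)
  expect_equal(nrow(tr$rects), 1L)
  expect_equal(tr$rects$seq_id, "c2")
  expect_equal(c(tr$rects$win_start, tr$rects$win_end), c(100, 300))
  p$zoom_region <- parse_region("c9:1:10")
  expect_error(build_track(g, p, 0, base_scale = 0.1), "absent from genome")
})

test_that("transforms with zoom 1 are isometries (random angles)", {
  set.seed(1)
  for (i in 1:50) {
    tr <- simple_track(params = list(rotate_chr = runif(1, 0, 360),
                                     move_to_x = runif(1, -500, 500),
                                     move_to_y = runif(1, -500, 500)))
    p <- matrix(runif(8, -100, 100), ncol = 2)
    q <- affine_apply(tr$transform, p)
    expect_equal(as.numeric(dist(q)), as.numeric(dist(p)), tolerance = 1e-9)
  }
})

test_that("clipping drops, clips and rescales partner intervals proportionally", {
  ta <- simple_track(len = 1000)
  tb_full <- simple_track(len = 1000)
  tb <- tb_full; tb$rects$win_start <- 1; tb$rects$win_end <- 1000

  # window on A restricted to 251..750
  ta$rects$win_start <- 251; ta$rects$win_end <- 750
  links <- link_set_from_rows(list(
    link_row("c1", 300, 700, "c1", 100, 500),          # fully inside
    link_row("c1", 1, 200, "c1", 600, 800),            # fully left of A window
    link_row("c1", 1, 500, "c1", 101, 600),            # 50% overlap on A
    link_row("c1", 1, 500, "c1", 101, 600, "inverted")))
  res <- clip_links_to_windows(links, ta, tb)
  expect_equal(res$counts, list(total = 4L, kept = 3L, clipped = 2L, dropped = 1L))
  expect_true(res$dropped[2])
  lk <- res$links
  # untouched link unchanged
  expect_equal(c(lk$start_a[1], lk$end_a[1], lk$start_b[1], lk$end_b[1]),
               c(300, 700, 100, 500))
  # brute-force proportional oracle for the 50%-clip:
  # A 1..500 clipped to 251..500 -> fractions (250/499, 1); B 101..600
  u0 <- (251 - 1) / (500 - 1)
  expect_equal(c(lk$start_a[2], lk$end_a[2]), c(251, 500))
  expect_equal(lk$start_b[2], 101 + u0 * (600 - 101))
  expect_equal(lk$end_b[2], 600)
  # inverted: the cut happens at B's opposite end
  expect_equal(lk$start_b[3], 101)
  expect_equal(lk$end_b[3], 101 + (1 - u0) * (600 - 101))
})

test_that("clipping conserves counts and windows on random configurations", {
  set.seed(5)
  for (rep in 1:25) {
    ta <- simple_track(len = 10000)
    tb <- simple_track(len = 10000)
    wa <- sort(sample(10000, 2)); wb <- sort(sample(10000, 2))
    ta$rects$win_start <- wa[1]; ta$rects$win_end <- wa[2]
    tb$rects$win_start <- wb[1]; tb$rects$win_end <- wb[2]
    rows <- lapply(1:20, function(i) {
      sa <- sample(9000, 1); sb <- sample(9000, 1)
      link_row("c1", sa, sa + sample(1000, 1), "c1", sb, sb + sample(1000, 1),
               sample(c("same", "inverted"), 1))
    })
    links <- link_set_from_rows(rows)
    res <- clip_links_to_windows(links, ta, tb)
    expect_equal(res$counts$kept + res$counts$dropped, res$counts$total)
    lk <- res$links
    if (nrow(lk) > 0) {
      expect_true(all(lk$start_a >= wa[1] & lk$end_a <= wa[2]))
      expect_true(all(lk$start_b >= wb[1] & lk$end_b <= wb[2]))
      expect_true(all(lk$start_a <= lk$end_a & lk$start_b <= lk$end_b))
    }
  }
})

test_that("ribbon anchors follow StyleUpDown edges and cross when inverted", {
  ta <- simple_track(slot_y = 0)      # chromosome spans y 0..20 (chr_height 20)
  tb <- simple_track(slot_y = 100)
  lp <- default_link_params()
  lk <- link_row("c1", 100, 400, "c1", 200, 500)

  lp$style_up_down <- "UpDown"
  an <- compute_ribbon_anchors(lk, ta, tb, lp)
  expect_equal(an$a_start[2], 0)          # A's top edge
  expect_equal(an$b_start[2], 100 + 20)   # B's bottom edge
  lp$style_up_down <- "DownDown"
  an2 <- compute_ribbon_anchors(lk, ta, tb, lp)
  expect_equal(an2$a_start[2], 20)
  expect_equal(an2$b_start[2], 120)

  lk_inv <- link_row("c1", 100, 400, "c1", 200, 500, "inverted")
  an3 <- compute_ribbon_anchors(lk_inv, ta, tb, lp)
  expect_equal(an3$b_start, an2$b_end)    # b anchors swapped
  expect_equal(an3$b_end, an2$b_start)
})

test_that("bp order equals x order within a rect (monotonicity property)", {
  set.seed(8)
  for (i in 1:20) {
    len <- sample(1000:100000, 1)
    tr <- simple_track(len = len, base_scale = runif(1, 1e-4, 1e-2))
    pos <- sort(sample(len, 10))
    xs <- bp_to_canvas(tr, "c1", pos, "top")[, 1]
    expect_true(all(diff(xs) > 0))
  }
})

test_that("layout_scene builds the layered scene deterministically", {
  tc <- tiny_config(extra = c("SetParaFor=GenomeALL", "ShowCoordinates=1"))
  sc <- layout_scene(tc$model)
  expect_s3_class(sc, "syn_scene")
  expect_length(sc$layers$ribbons, 1L)
  expect_length(sc$layers$tracks, 3L)       # 2 + 1 chromosomes
  expect_length(sc$layers$labels, 2L)
  expect_gt(length(sc$layers$axes), 0L)
  sc2 <- layout_scene(tc$model)
  expect_identical(scene_to_json(sc), scene_to_json(sc2))

  # empty link file -> no ribbon layer entries
  tc2 <- tiny_config(link_lines = "# none")
  sc3 <- layout_scene(tc2$model)
  expect_length(sc3$layers$ribbons, 0L)
})

test_that("triangle fixture yields three tracks with distinct nonzero rotations", {
  fx <- make_fixture(tempfile("tri"), n_genomes = 3, seed = 4, layout = "triangle")
  model <- parse_config(fx$config)
  rot <- vapply(1:3, function(i) resolve_genome_params(model, i)$rotate_chr, 0)
  expect_true(all(rot != 0))
  expect_equal(length(unique(rot)), 3L)
  sc <- layout_scene(model)
  expect_length(sc$tracks, 3L)
})
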