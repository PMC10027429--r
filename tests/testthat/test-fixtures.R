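tree_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  vapply(files, function(f) paste(readLines(file.path(dir, f)), collapse = "\n"), "")
}

test_that("fixture generation is byte-deterministic in the seed", {
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  make_fixture(d1, seed = 7)
  make_fixture(d2, seed = 7)
  expect_identical(tree_digest(d1), tree_digest(d2))
  d3 <- tempfile("fxc")
  make_fixture(d3, seed = 8)
  expect_false(identical(tree_digest(d1), tree_digest(d3)))
})

test_that("inversion_fraction bounds hold and coordinates stay in range", {
  fx0 <- make_fixture(tempfile(), seed = 3, inversion_fraction = 0)
  expect_true(all(vapply(fx0$link_sets,
                         function(l) all(l$orientation == "same"), TRUE)))
  fx1 <- make_fixture(tempfile(), seed = 3, inversion_fraction = 1)
  expect_true(all(vapply(fx1$link_sets,
                         function(l) all(l$orientation == "inverted"), TRUE)))

  fx <- make_fixture(tempfile(), seed = 9, n_genomes = 4, n_links = 12)
  for (i in seq_along(fx$link_sets)) {
    lk <- fx$link_sets[[i]]
    ga <- fx$genome_defs[[i]]$chroms
    gb <- fx$genome_defs[[i + 1]]$chroms
    expect_true(all(lk$end_a <= ga$end[match(lk$seq_a, ga$seq_id)]))
    expect_true(all(lk$end_b <= gb$end[match(lk$seq_b, gb$seq_id)]))
    expect_true(all(lk$start_a >= 1 & lk$start_b >= 1))
  }
  expect_error(make_fixture(tempfile(), n_genomes = 1), "between 2 and 20")
  expect_error(make_fixture(tempfile(), n_genomes = 21), "between 2 and 20")
})

test_that("dialect files re-encode exactly the generated native links", {
  fx <- make_fixture(tempfile(), seed = 5, n_genomes = 3, n_links = 10,
                     inversion_fraction = 0.4)
  for (i in seq_along(fx$link_sets)) {
    tag <- sprintf("%d_%d", i, i + 1)
    d <- fx$dialects[[tag]]
    native <- fx$link_sets[[i]]
    expect_same_links(convert_paf(d$paf)$links, native)
    expect_same_links(convert_mummer_coords(d$coords), native)
    expect_same_links(convert_syri(d$syri), native)
    expect_same_links(convert_mcscanx(d$collinearity, d$genes), native)
  }
})

test_that("the generated configuration is directly plottable", {
  fx <- make_fixture(tempfile(), seed = 6, n_genomes = 2)
  model <- parse_config(fx$config)
  expect_length(model$genomes, 2L)
  sc <- layout_scene(model)
  expect_length(sc$layers$ribbons, nrow(fx$link_sets[[1]]))
})
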