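# Shared helpers: tiny on-disk fixtures built in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A minimal two-genome scene on disk; returns the parsed config_model and
# the paths involved.
tiny_config <- function(dir = tempfile("conf"),
                        genome_lines = list(
                          c("a1\t1\t1000", "a2\t1\t500"),
                          c("b1\t1\t800")),
                        link_lines = c("a1\t100\t400\tb1\t200\t500"),
                        extra = character(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpaths <- character(length(genome_lines))
  for (i in seq_along(genome_lines)) {
    gpaths[i] <- file.path(dir, sprintf("g%d.genome", i))
    writeLines(genome_lines[[i]], gpaths[i])
  }
  lpath <- file.path(dir, "l12.links")
  writeLines(link_lines, lpath)
  conf <- file.path(dir, "plot.conf")
  writeLines(c(sprintf("Genome = %s", basename(gpaths)),
               sprintf("Link = %s 1 2", basename(lpath)),
               extra), conf)
  list(model = parse_config(conf), config = conf, genomes = gpaths, link = lpath,
       dir = dir)
}

# Canonical comparable form of a link_set (coordinates + orientation only).
link_key <- function(lk) {
  d <- as.data.frame(lk)[c("seq_a", "start_a", "end_a",
                           "seq_b", "start_b", "end_b", "orientation")]
  rownames(d) <- NULL
  d
}

expect_same_links <- function(got, want) {
  expect_equal(link_key(got), link_key(want), ignore_attr = TRUE)
}

# Identity-transform track over one chromosome, for geometry tests.
simple_track <- function(len = 1000, base_scale = 0.1, params = list(),
                         slot_y = 0) {
  p <- utils::modifyList(default_genome_params(), params)
  g <- new_genome_def_test("g", data.frame(seq_id = "c1", start = 1, end = len,
                                           stringsAsFactors = FALSE))
  build_track(g, p, default_slot_y = slot_y, base_scale = base_scale,
              default_x = 0)
}

new_genome_def_test <- function(name, chroms) {
  chroms$attrs <- rep(list(attr_map()), nrow(chroms))
  g <- list(name = name, chroms = chroms)
  class(g) <- "genome_def"
  g
}

# One-row link list for anchor/clip tests.
link_row <- function(seq_a, sa, ea, seq_b, sb, eb, orientation = "same") {
  list(seq_a = seq_a, start_a = sa, end_a = ea,
       seq_b = seq_b, start_b = sb, end_b = eb,
       orientation = orientation, attrs = attr_map())
}

link_set_from_rows <- function(rows) {
  df <- data.frame(
    seq_a = vapply(rows, `[[`, "", "seq_a"),
    start_a = vapply(rows, `[[`, 0, "start_a"),
    end_a = vapply(rows, `[[`, 0, "end_a"),
    seq_b = vapply(rows, `[[`, "", "seq_b"),
    start_b = vapply(rows, `[[`, 0, "start_b"),
    end_b = vapply(rows, `[[`, 0, "end_b"),
    orientation = vapply(rows, `[[`, "", "orientation"),
    stringsAsFactors = FALSE)
  df$attrs <- lapply(rows, `[[`, "attrs")
  class(df) <- c("link_set", "data.frame")
  df
}
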