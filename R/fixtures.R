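# Deterministic toy-dataset generator: native genome/link/feature files, a
# ready-to-run configuration, and equivalent PAF / show-coords / SyRI /
# MCScanX dialect files encoding the same links (the converters' principal
# oracle). A single integer seed fully determines every output byte; each
# file type draws from its own derived PRNG stream so adding one file type
# never perturbs the others.

fixture_stream <- function(seed, k) {
  # derived sub-seed, kept well below 2^31
  set.seed((as.integer(seed) %% 1000000L) * 101L + k)
}

#' Generate a deterministic multi-genome toy dataset
#'
#' Writes, under `out_dir`: one genome file per genome (`g<i>.genome`), one
#' link file per adjacent genome pair (`links_<i>_<j>.links`), a feature file
#' on genome 1, a ready-to-run `plot.conf`, and — for every adjacent pair —
#' dialect files (`pair_<i>_<j>.paf`, `.coords`, `.syri.out`,
#' `.collinearity` + `genes_<i>_<j>.tsv`) that encode exactly the same links,
#' so converting them must reproduce the native link set.
#'
#' Defaults describe a small but structured comparative-genomics scene: three
#' genomes of two chromosomes in the 0.5-2 Mb range, eight syntenic blocks
#' per adjacent pair of which roughly one fifth are inversions, and six
#' highlighted features.
#'
#' @param out_dir output directory (created if needed)
#' @param n_genomes number of genomes, 2..20
#' @param chroms_per_genome chromosomes per genome
#' @param chrom_length_range numeric length-2: min/max chromosome length (bp)
#' @param n_links syntenic blocks per adjacent genome pair
#' @param inversion_fraction fraction of links inverted, in `[0, 1]`
#' @param n_features highlighted regions placed on genome 1
#' @param seed integer seed; fully determines all output bytes
#' @param layout `"stacked"` (default) or `"triangle"` (3 genomes: adds
#'   distinct nonzero rotations for a triangular arrangement)
#' @return invisible list: file paths (`config`, `genomes`, `links`,
#'   `features`, `dialects`) plus the in-memory `genome_defs` and
#'   `link_sets` used to write them
#' @export
make_fixture <- function(out_dir,
                         n_genomes = 3,
                         chroms_per_genome = 2,
                         chrom_length_range = c(5e5, 2e6),
                         n_links = 8,
                         inversion_fraction = 0.2,
                         n_features = 6,
                         seed = 1,
                         layout = c("stacked", "triangle")) {
  layout <- match.arg(layout)
  if (n_genomes < 2 || n_genomes > 20) {
    stop("n_genomes must be between 2 and 20", call. = FALSE)
  }
  stopifnot(chroms_per_genome >= 1, n_links >= 0, n_features >= 0,
            inversion_fraction >= 0, inversion_fraction <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory %s", out_dir), call. = FALSE)

  # --- stream 1: genomes
  fixture_stream(seed, 1L)
  genome_defs <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    lens <- round(stats::runif(chroms_per_genome,
                               chrom_length_range[1L], chrom_length_range[2L]))
    chroms <- data.frame(seq_id = sprintf("G%d_chr%d", i, seq_len(chroms_per_genome)),
                         start = 1, end = lens, stringsAsFactors = FALSE)
    chroms$attrs <- rep(list(attr_map()), chroms_per_genome)
    genome_defs[[i]] <- new_genome_def(sprintf("genome%d", i), chroms)
  }

  # --- stream 2: links between adjacent genomes
  fixture_stream(seed, 2L)
  link_sets <- list()
  for (i in seq_len(n_genomes - 1L)) {
    ga <- genome_defs[[i]]$chroms
    gb <- genome_defs[[i + 1L]]$chroms
    rows <- vector("list", n_links)
    for (r in seq_len(n_links)) {
      ca <- sample.int(nrow(ga), 1L)
      cb <- sample.int(nrow(gb), 1L)
      len_a <- round(stats::runif(1, 0.02, 0.25) * (ga$end[ca] - 1))
      len_b <- round(stats::runif(1, 0.02, 0.25) * (gb$end[cb] - 1))
      sa <- sample.int(ga$end[ca] - len_a, 1L)
      sb <- sample.int(gb$end[cb] - len_b, 1L)
      inv <- stats::runif(1) < inversion_fraction
      rows[[r]] <- list(seq_a = ga$seq_id[ca], start_a = sa, end_a = sa + len_a,
                        seq_b = gb$seq_id[cb], start_b = sb, end_b = sb + len_b,
                        orientation = if (inv) "inverted" else "same",
                        attrs = attr_map())
    }
    link_sets[[i]] <- link_rows_to_set(rows)
  }

  # --- stream 3: features on genome 1
  fixture_stream(seed, 3L)
  g1 <- genome_defs[[1L]]$chroms
  feat_types <- c("CDS", "UTR", "TE", "SNP")
  features <- NULL
  if (n_features > 0) {
    ci <- sample.int(nrow(g1), n_features, replace = TRUE)
    len <- round(stats::runif(n_features, 0.005, 0.03) * (g1$end[ci] - 1))
    fs <- vapply(seq_len(n_features),
                 function(r) sample.int(g1$end[ci[r]] - len[r], 1L), 0L)
    features <- data.frame(seq_id = g1$seq_id[ci], start = fs, end = fs + len,
                           stringsAsFactors = FALSE)
    features$attrs <- lapply(seq_len(n_features), function(r) {
      attr_map("feature", feat_types[(r - 1L) %% length(feat_types) + 1L])
    })
  }

  # --- write native files
  genome_paths <- character(n_genomes)
  for (i in seq_len(n_genomes)) {
    genome_paths[i] <- file.path(out_dir, sprintf("g%d.genome", i))
    write_genome_file(genome_defs[[i]], genome_paths[i])
  }
  link_paths <- character(length(link_sets))
  for (i in seq_along(link_sets)) {
    link_paths[i] <- file.path(out_dir, sprintf("links_%d_%d.links", i, i + 1L))
    write_link_file(link_sets[[i]], link_paths[i])
  }
  feature_path <- NULL
  if (!is.null(features)) {
    feature_path <- file.path(out_dir, "features_g1.txt")
    write_feature_file(features, feature_path)
  }

  # --- dialect files re-encoding the same links
  dialects <- list()
  for (i in seq_along(link_sets)) {
    tag <- sprintf("%d_%d", i, i + 1L)
    lk <- link_sets[[i]]
    ga <- genome_defs[[i]]$chroms
    gb <- genome_defs[[i + 1L]]$chroms
    alen <- function(df, r) df$end_a[r] - df$start_a[r] + 1

    # PAF: query = genome A, target = genome B; 0-based half-open
    paf_path <- file.path(out_dir, sprintf("pair_%s.paf", tag))
    paf <- vapply(seq_len(nrow(lk)), function(r) {
      qlen <- ga$end[match(lk$seq_a[r], ga$seq_id)]
      tlen <- gb$end[match(lk$seq_b[r], gb$seq_id)]
      la <- lk$end_a[r] - lk$start_a[r] + 1
      lb <- lk$end_b[r] - lk$start_b[r] + 1
      paste(lk$seq_a[r], fmt_bp(qlen), fmt_bp(lk$start_a[r] - 1), fmt_bp(lk$end_a[r]),
            if (lk$orientation[r] == "inverted") "-" else "+",
            lk$seq_b[r], fmt_bp(tlen), fmt_bp(lk$start_b[r] - 1), fmt_bp(lk$end_b[r]),
            fmt_bp(min(la, lb)), fmt_bp(max(la, lb)), "60", sep = "\t")
    }, "")
    writeLines(paf, paf_path)

    # MUMmer show-coords -T: ref = genome A, qry = genome B; banner + header
    coords_path <- file.path(out_dir, sprintf("pair_%s.coords", tag))
    coords <- c(sprintf("%s.fa %s.fa", sprintf("g%d", i), sprintf("g%d", i + 1L)),
                "NUCMER", "",
                "[S1]\t[E1]\t[S2]\t[E2]\t[LEN 1]\t[LEN 2]\t[% IDY]\t[TAGS]")
    coords <- c(coords, vapply(seq_len(nrow(lk)), function(r) {
      la <- lk$end_a[r] - lk$start_a[r] + 1
      lb <- lk$end_b[r] - lk$start_b[r] + 1
      inv <- lk$orientation[r] == "inverted"
      s2 <- if (inv) lk$end_b[r] else lk$start_b[r]
      e2 <- if (inv) lk$start_b[r] else lk$end_b[r]
      paste(fmt_bp(lk$start_a[r]), fmt_bp(lk$end_a[r]), fmt_bp(s2), fmt_bp(e2),
            fmt_bp(la), fmt_bp(lb), "97.50", lk$seq_a[r], lk$seq_b[r], sep = "\t")
    }, ""))
    writeLines(coords, coords_path)

    # SyRI: ref interval cols 1-3, qry cols 6-8, class col 11
    syri_path <- file.path(out_dir, sprintf("pair_%s.syri.out", tag))
    syri <- vapply(seq_len(nrow(lk)), function(r) {
      inv <- lk$orientation[r] == "inverted"
      type <- if (inv) "INV" else "SYN"
      s2 <- if (inv) lk$end_b[r] else lk$start_b[r]
      e2 <- if (inv) lk$start_b[r] else lk$end_b[r]
      paste(lk$seq_a[r], fmt_bp(lk$start_a[r]), fmt_bp(lk$end_a[r]), "-", "-",
            lk$seq_b[r], fmt_bp(s2), fmt_bp(e2),
            sprintf("%s%d", type, r), "-", type, "-", sep = "\t")
    }, "")
    writeLines(syri, syri_path)

    # MCScanX: one 2-gene block per link; gene spans are the link endpoints
    coll_path <- file.path(out_dir, sprintf("pair_%s.collinearity", tag))
    genes_path <- file.path(out_dir, sprintf("genes_%s.tsv", tag))
    coll <- c("############### Parameters ###############",
              "# MATCH_SCORE: 50", "# generated fixture",
              "############### Statistics ###############")
    genes <- character(0)
    for (r in seq_len(nrow(lk))) {
      ori <- if (lk$orientation[r] == "inverted") "minus" else "plus"
      gA1 <- sprintf("A%s_%d_1", tag, r); gA2 <- sprintf("A%s_%d_2", tag, r)
      gB1 <- sprintf("B%s_%d_1", tag, r); gB2 <- sprintf("B%s_%d_2", tag, r)
      coll <- c(coll,
                sprintf("## Alignment %d: score=500.0 e_value=0 N=2 gA&gB %s", r - 1L, ori),
                sprintf("%3d-%3d:\t%s\t%s\t0", r - 1L, 0L, gA1, gB1),
                sprintf("%3d-%3d:\t%s\t%s\t0", r - 1L, 1L, gA2, gB2))
      genes <- c(genes,
                 paste(gA1, lk$seq_a[r], fmt_bp(lk$start_a[r]), fmt_bp(lk$start_a[r]), sep = "\t"),
                 paste(gA2, lk$seq_a[r], fmt_bp(lk$end_a[r]), fmt_bp(lk$end_a[r]), sep = "\t"),
                 paste(gB1, lk$seq_b[r], fmt_bp(lk$start_b[r]), fmt_bp(lk$start_b[r]), sep = "\t"),
                 paste(gB2, lk$seq_b[r], fmt_bp(lk$end_b[r]), fmt_bp(lk$end_b[r]), sep = "\t"))
    }
    writeLines(coll, coll_path)
    writeLines(genes, genes_path)

    dialects[[tag]] <- list(paf = paf_path, coords = coords_path,
                            syri = syri_path, collinearity = coll_path,
                            genes = genes_path)
  }

  # --- configuration
  conf_path <- file.path(out_dir, "plot.conf")
  conf <- c("# generated fixture configuration",
            sprintf("Genome = %s", basename(genome_paths)))
  if (!is.null(feature_path)) conf <- c(conf, sprintf("Feature = 1 %s", basename(feature_path)))
  conf <- c(conf, sprintf("Link = %s %d %d", basename(link_paths),
                          seq_along(link_paths), seq_along(link_paths) + 1L))
  conf <- c(conf,
            "",
            "SetParaFor = global",
            "canvas_width = 1000",
            "slot_pitch = 110",
            "",
            "SetParaFor = GenomeALL",
            "ShowCoordinates = 1",
            "ChrHeight = 18")
  if (layout == "triangle") {
    if (n_genomes != 3) stop("triangle layout needs exactly 3 genomes", call. = FALSE)
    conf <- c(conf,
              "",
              "SetParaFor = Genome1", "RotateChr = 30", "MoveToX = 120", "MoveToY = 140",
              "",
              "SetParaFor = Genome2", "RotateChr = 330", "MoveToX = 420", "MoveToY = 360",
              "",
              "SetParaFor = Genome3", "RotateChr = 90", "MoveToX = 820", "MoveToY = 120",
              "",
              "SetParaFor = Link1", "StyleUpDown = DownDown", "Style = 4")
  }
  writeLines(conf, conf_path)

  invisible(list(config = conf_path,
                 genomes = genome_paths,
                 links = link_paths,
                 features = feature_path,
                 dialects = dialects,
                 genome_defs = genome_defs,
                 link_sets = link_sets,
                 features_df = features))
}
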