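# Converters from third-party whole-genome-alignment outputs into the native
# link format. Native coordinates are 1-based fully closed; PAF input is
# 0-based half-open and converted.

link_rows_to_set <- function(rows) {
  if (length(rows) == 0L) return(new_link_set(empty_link_df()))
  df <- data.frame(
    seq_a = vapply(rows, `[[`, "", "seq_a"),
    start_a = vapply(rows, `[[`, 0, "start_a"),
    end_a = vapply(rows, `[[`, 0, "end_a"),
    seq_b = vapply(rows, `[[`, "", "seq_b"),
    start_b = vapply(rows, `[[`, 0, "start_b"),
    end_b = vapply(rows, `[[`, 0, "end_b"),
    orientation = vapply(rows, `[[`, "", "orientation"),
    stringsAsFactors = FALSE)
  df$attrs <- lapply(rows, function(r) r$attrs %||% attr_map())
  new_link_set(df)
}

#' Convert minimap2 PAF alignments to native links
#'
#' One link per PAF line whose alignment-block length (column 11) is at least
#' `min_block_len`. The query interval becomes side A and the target interval
#' side B; strand `-` marks the link inverted. PAF's 0-based half-open
#' coordinates become 1-based closed (`start+1`, `end`), which preserves
#' interval lengths. Query and target names/lengths (columns 1-2 and 6-7) are
#' collected into sequence-length tables. Malformed lines are skipped with a
#' warning; the skip count is reported in the result.
#'
#' @param path PAF file (plain or gzipped)
#' @param min_block_len minimum alignment block length in bp (default 0)
#' @return list with `links` (a `link_set`), `query_lengths` and
#'   `target_lengths` (data frames `seq_id`,`length`), and `n_skipped`
#' @export
convert_paf <- function(path, min_block_len = 0) {
  lines <- read_text_lines(path)
  rows <- list()
  qlen <- list(); tlen <- list()
  n_skipped <- 0L
  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 12L) {
      warning(sprintf("%s, line %d: malformed PAF line (<12 columns), skipped",
                      path, i), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    num <- suppressWarnings(as.numeric(tok[c(2:4, 7:12)]))
    if (anyNA(num) || !(tok[5L] %in% c("+", "-"))) {
      warning(sprintf("%s, line %d: malformed PAF line (bad numeric/strand fields), skipped",
                      path, i), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    qname <- tok[1L]; tname <- tok[6L]
    qlen[[qname]] <- num[1L]; tlen[[tname]] <- num[4L]
    block_len <- num[8L]   # PAF column 11
    if (block_len < min_block_len) next
    rows[[length(rows) + 1L]] <- list(
      seq_a = qname, start_a = num[2L] + 1, end_a = num[3L],
      seq_b = tname, start_b = num[5L] + 1, end_b = num[6L],
      orientation = if (tok[5L] == "-") "inverted" else "same",
      attrs = attr_map())
  }
  list(links = link_rows_to_set(rows),
       query_lengths = data.frame(seq_id = names(qlen),
                                  length = as.numeric(unlist(qlen %||% list(0))[names(qlen)]),
                                  stringsAsFactors = FALSE),
       target_lengths = data.frame(seq_id = names(tlen),
                                   length = as.numeric(unlist(tlen %||% list(0))[names(tlen)]),
                                   stringsAsFactors = FALSE),
       n_skipped = n_skipped)
}

#' Convert MUMmer show-coords tabular output to native links
#'
#' Supports the tab/space-delimited dialect of `show-coords -T` (with or
#' without the banner and `[S1] [E1] ...` header). Data rows carry the
#' reference interval (columns 1-2, side A), query interval (columns 3-4,
#' side B), two lengths, percent identity and finally the reference and query
#' sequence IDs. A descending query interval marks an inverted block.
#'
#' @param path show-coords output (plain or gzipped)
#' @return a `link_set`
#' @export
convert_mummer_coords <- function(path) {
  lines <- read_text_lines(path)
  rows <- list()
  saw_any_data <- FALSE
  for (i in seq_along(lines)) {
    s <- trimws(lines[i])
    if (!nzchar(s)) next
    tok <- split_ws(s)
    # banner / NUCMER / [S1]... header lines fail the numeric test and are skipped
    if (length(tok) < 9L) next
    num <- suppressWarnings(as.numeric(tok[1:7]))
    if (anyNA(num)) next
    saw_any_data <- TRUE
    s1 <- num[1L]; e1 <- num[2L]; s2 <- num[3L]; e2 <- num[4L]
    ref_id <- tok[length(tok) - 1L]
    qry_id <- tok[length(tok)]
    rows[[length(rows) + 1L]] <- list(
      seq_a = ref_id, start_a = min(s1, e1), end_a = max(s1, e1),
      seq_b = qry_id, start_b = min(s2, e2), end_b = max(s2, e2),
      orientation = if (xor(e1 < s1, e2 < s2)) "inverted" else "same",
      attrs = attr_map())
  }
  if (!saw_any_data && any(vapply(lines, is_data_line, TRUE))) {
    stop(sprintf(
      "%s: could not detect show-coords tabular structure (expected `show-coords -T` rows: S1 E1 S2 E2 LEN1 LEN2 %%IDY ... REF QRY)",
      path), call. = FALSE)
  }
  link_rows_to_set(rows)
}

#' Convert MCScanX collinearity blocks to native links
#'
#' Each `## Alignment` block lists collinear gene pairs; with a gene position
#' table (`gene_id seq start end`) every block becomes one link spanning
#' `min(start)..max(end)` of the block's genes on each side. Blocks annotated
#' `minus` are inverted.
#'
#' @param collinearity_path MCScanX `.collinearity` file
#' @param gene_pos_path tab/space-delimited table: gene_id, seq, start, end
#' @return a `link_set`
#' @export
convert_mcscanx <- function(collinearity_path, gene_pos_path) {
  pos_lines <- read_text_lines(gene_pos_path)
  gene_seq <- character(0); gene_start <- numeric(0); gene_end <- numeric(0)
  for (i in seq_along(pos_lines)) {
    if (!is_data_line(pos_lines[i])) next
    tok <- split_ws(pos_lines[i])
    if (length(tok) < 4L) {
      stop(sprintf("%s, line %d: expected gene_id seq start end", gene_pos_path, i),
           call. = FALSE)
    }
    gene_seq[tok[1L]] <- tok[2L]
    gene_start[tok[1L]] <- parse_coord(tok[3L], "start", gene_pos_path, i)
    gene_end[tok[1L]] <- parse_coord(tok[4L], "end", gene_pos_path, i)
  }

  lines <- read_text_lines(collinearity_path)
  rows <- list()
  blk_a <- character(0); blk_b <- character(0); blk_minus <- FALSE
  missing_ids <- character(0)

  flush_block <- function() {
    if (length(blk_a) == 0L) return()
    miss <- setdiff(c(blk_a, blk_b), names(gene_seq))
    if (length(miss) > 0L) {
      missing_ids <<- unique(c(missing_ids, miss))
      return()
    }
    rows[[length(rows) + 1L]] <<- list(
      seq_a = gene_seq[[blk_a[1L]]],
      start_a = min(gene_start[blk_a]), end_a = max(gene_end[blk_a]),
      seq_b = gene_seq[[blk_b[1L]]],
      start_b = min(gene_start[blk_b]), end_b = max(gene_end[blk_b]),
      orientation = if (blk_minus) "inverted" else "same",
      attrs = attr_map())
  }

  for (line in lines) {
    s <- trimws(line)
    if (startsWith(s, "## Alignment")) {
      flush_block()
      blk_a <- character(0); blk_b <- character(0)
      blk_minus <- grepl("\\bminus\\b", s)
    } else if (startsWith(s, "#") || !nzchar(s)) {
      next
    } else {
      # "  0-  0:   geneA   geneB   e-value"
      body <- sub("^[^:]*:", "", s)
      tok <- split_ws(body)
      if (length(tok) >= 2L) {
        blk_a <- c(blk_a, tok[1L])
        blk_b <- c(blk_b, tok[2L])
      }
    }
  }
  flush_block()
  if (length(missing_ids) > 0L) {
    stop(sprintf("%s: gene ID(s) absent from position table %s: %s",
                 collinearity_path, gene_pos_path,
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  link_rows_to_set(rows)
}

#' Default fill palette for SyRI annotation classes
#'
#' Fixed 8-entry table mapping structural-annotation classes to fill colors;
#' unknown classes fall back to the `OTHER` entry.
#' @return named character vector of colors
#' @export
syri_palette <- function() {
  c(SYN   = "#bdbdbd",
    INV   = "#e6550d",
    TRANS = "#31a354",
    DUP   = "#3182bd",
    INVTR = "#756bb1",
    INVDP = "#17a2b8",
    NOTAL = "#f0f0f0",
    OTHER = "#636363")
}

# annotation classes that never yield a two-sided link
.syri_excluded <- c("SNP", "INS", "DEL", "CPG", "CPL", "HDR", "TDM", "NOTAL")

#' Convert SyRI structural-annotation output to native links
#'
#' Reads SyRI's tab-delimited output (reference interval in columns 1-3,
#' query interval in columns 6-8, annotation class in column 11). Only
#' interval-bearing top-level record classes are kept: alignment-level child
#' records (classes ending in `AL`), single-sided records (`NOTAL`) and point
#' annotations (`SNP`, `INS`, `DEL`, ...) are dropped. Each kept record's
#' class is stored in the `svtype` attribute with a default fill color from
#' [syri_palette()]; `INV`-class records (and descending query intervals) are
#' marked inverted. Unknown classes are kept with the fallback color and a
#' warning.
#'
#' @param path SyRI output file (plain or gzipped)
#' @return a `link_set`; each record carries `svtype` and `fill` attributes
#' @export
convert_syri <- function(path) {
  lines <- read_text_lines(path)
  pal <- syri_palette()
  rows <- list()
  unknown <- character(0)
  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    tok <- split_ws(lines[i])
    if (length(tok) < 11L) next
    type <- tok[11L]
    if (type %in% .syri_excluded) next
    if (grepl("AL$", type) && type %in% c("SYNAL", "INVAL", "TRANSAL", "DUPAL", "INVTRAL", "INVDPAL")) next
    coords <- suppressWarnings(as.numeric(tok[c(2, 3, 7, 8)]))
    if (anyNA(coords)) next   # e.g. "-" placeholders on one side
    known <- type %in% names(pal)
    if (!known && !(type %in% unknown)) {
      unknown <- c(unknown, type)
      warning(sprintf("%s: unknown SyRI annotation type '%s'; kept with default color",
                      path, type), call. = FALSE)
    }
    fill <- if (known) pal[[type]] else pal[["OTHER"]]
    inverted <- startsWith(type, "INV") || coords[4L] < coords[3L]
    rows[[length(rows) + 1L]] <- list(
      seq_a = tok[1L], start_a = min(coords[1:2]), end_a = max(coords[1:2]),
      seq_b = tok[6L], start_b = min(coords[3:4]), end_b = max(coords[3:4]),
      orientation = if (inverted) "inverted" else "same",
      attrs = attr_map(c("svtype", "fill"), c(type, fill)))
  }
  link_rows_to_set(rows)
}
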