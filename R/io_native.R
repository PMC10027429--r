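# Native text formats: genome (sequence length) files, link files, feature
# (highlight region) files. All are whitespace-delimited, "#" starts a comment
# line, coordinates are 1-based fully-closed intervals.

new_genome_def <- function(name, chroms) {
  structure(list(name = name, chroms = chroms), class = "genome_def")
}

new_link_set <- function(df) {
  stopifnot(all(c("seq_a", "start_a", "end_a", "seq_b", "start_b", "end_b",
                  "orientation", "attrs") %in% names(df)))
  class(df) <- c("link_set", "data.frame")
  df
}

empty_link_df <- function() {
  data.frame(seq_a = character(0), start_a = numeric(0), end_a = numeric(0),
             seq_b = character(0), start_b = numeric(0), end_b = numeric(0),
             orientation = character(0), attrs = I(list()),
             stringsAsFactors = FALSE)
}

#' Read a genome (sequence length) file
#'
#' Each data line has at least three ordered columns: sequence ID, start, end
#' (1-based, closed). Further tokens are unordered `key=value` attributes.
#' Lines starting with `#` and blank lines are skipped. Sequence IDs must be
#' unique within a genome and file order is preserved.
#'
#' @param path path to a plain or gzipped text file
#' @param name genome label; defaults to the file name without extension
#' @return a `genome_def`: list with `name` and a `chroms` data frame
#'   (`seq_id`, `start`, `end`, list-column `attrs`)
#' @export
read_genome_file <- function(path, name = NULL) {
  lines <- read_text_lines(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  seq_id <- character(0); start <- numeric(0); end <- numeric(0)
  attrs <- list()
  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    tok <- split_ws(lines[i])
    if (length(tok) < 3L) {
      stop(sprintf("%s, line %d: expected >=3 columns (seq_id start end), got %d",
                   path, i, length(tok)), call. = FALSE)
    }
    s <- parse_coord(tok[2L], "start", path, i)
    e <- parse_coord(tok[3L], "end", path, i)
    if (s > e) {
      stop(sprintf("%s, line %d: start (%s) > end (%s)", path, i, tok[2L], tok[3L]),
           call. = FALSE)
    }
    if (s < 1) {
      stop(sprintf("%s, line %d: start must be >= 1", path, i), call. = FALSE)
    }
    if (tok[1L] %in% seq_id) {
      stop(sprintf("%s, line %d: duplicate sequence ID '%s'", path, i, tok[1L]),
           call. = FALSE)
    }
    seq_id <- c(seq_id, tok[1L]); start <- c(start, s); end <- c(end, e)
    attrs[[length(attrs) + 1L]] <- parse_attr_fields(tok[-(1:3)], path, i)
  }
  chroms <- data.frame(seq_id = seq_id, start = start, end = end,
                       stringsAsFactors = FALSE)
  chroms$attrs <- attrs
  new_genome_def(name, chroms)
}

#' Read a link file
#'
#' The first six columns are two intervals of a syntenic block:
#' `seqA startA endA seqB startB endB`; later tokens are `key=value`
#' attributes. An inverted block is encoded by exactly one of the two
#' intervals having `end < start`; records are normalized to ascending
#' coordinates with the sign kept in the `orientation` column
#' (`"same"` or `"inverted"`).
#'
#' @param path path to a plain or gzipped link file
#' @return a `link_set` data frame
#' @export
read_link_file <- function(path) {
  lines <- read_text_lines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    tok <- split_ws(lines[i])
    if (length(tok) < 6L) {
      stop(sprintf("%s, line %d: expected >=6 columns (seqA startA endA seqB startB endB), got %d",
                   path, i, length(tok)), call. = FALSE)
    }
    sa <- parse_coord(tok[2L], "startA", path, i)
    ea <- parse_coord(tok[3L], "endA", path, i)
    sb <- parse_coord(tok[5L], "startB", path, i)
    eb <- parse_coord(tok[6L], "endB", path, i)
    inv_a <- ea < sa
    inv_b <- eb < sb
    orientation <- if (xor(inv_a, inv_b)) "inverted" else "same"
    rows[[length(rows) + 1L]] <- list(
      seq_a = tok[1L], start_a = min(sa, ea), end_a = max(sa, ea),
      seq_b = tok[4L], start_b = min(sb, eb), end_b = max(sb, eb),
      orientation = orientation,
      attrs = parse_attr_fields(tok[-(1:6)], path, i))
  }
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
  df$attrs <- lapply(rows, `[[`, "attrs")
  new_link_set(df)
}

#' Read a feature (highlight region) file
#'
#' Same shape as a genome file (`seq_id start end` plus attributes) but
#' sequence IDs may repeat; the conventional `feature` attribute carries a
#' type token such as `CDS`, `UTR`, `TE` or `SNP`.
#'
#' @param path path to a plain or gzipped feature file
#' @return data frame `seq_id`, `start`, `end`, list-column `attrs`
#' @export
read_feature_file <- function(path) {
  lines <- read_text_lines(path)
  seq_id <- character(0); start <- numeric(0); end <- numeric(0)
  attrs <- list()
  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    tok <- split_ws(lines[i])
    if (length(tok) < 3L) {
      stop(sprintf("%s, line %d: expected >=3 columns (seq_id start end), got %d",
                   path, i, length(tok)), call. = FALSE)
    }
    s <- parse_coord(tok[2L], "start", path, i)
    e <- parse_coord(tok[3L], "end", path, i)
    if (s > e) {
      stop(sprintf("%s, line %d: start (%s) > end (%s)", path, i, tok[2L], tok[3L]),
           call. = FALSE)
    }
    a <- parse_attr_fields(tok[-(1:3)], path, i)
    ft <- attr_get(a, "feature")
    if (!is.null(ft) && !nzchar(trimws(ft))) {
      stop(sprintf("%s, line %d: empty feature type", path, i), call. = FALSE)
    }
    seq_id <- c(seq_id, tok[1L]); start <- c(start, s); end <- c(end, e)
    attrs[[length(attrs) + 1L]] <- a
  }
  out <- data.frame(seq_id = seq_id, start = start, end = end,
                    stringsAsFactors = FALSE)
  out$attrs <- attrs
  out
}

#' Write a genome file
#'
#' Inverse of [read_genome_file()]: `read_genome_file(write_genome_file(g))`
#' reproduces `g` exactly, attribute order included.
#'
#' @param genome a `genome_def`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_file <- function(genome, path) {
  stopifnot(inherits(genome, "genome_def"))
  if (nrow(genome$chroms) == 0L) {
    stop("refusing to write an empty genome (no chromosomes)", call. = FALSE)
  }
  ch <- genome$chroms
  lines <- vapply(seq_len(nrow(ch)), function(i) {
    paste(c(ch$seq_id[i], fmt_bp(ch$start[i]), fmt_bp(ch$end[i]),
            attrs_to_tokens(ch$attrs[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a link file
#'
#' Inverted records are serialized with the B interval descending
#' (`end_b < start_b`), the same convention the reader accepts.
#'
#' @param links a `link_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_link_file <- function(links, path) {
  if (nrow(links) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(links)), function(i) {
    b1 <- links$start_b[i]; b2 <- links$end_b[i]
    if (identical(links$orientation[i], "inverted")) { tmp <- b1; b1 <- b2; b2 <- tmp }
    paste(c(links$seq_a[i], fmt_bp(links$start_a[i]), fmt_bp(links$end_a[i]),
            links$seq_b[i], fmt_bp(b1), fmt_bp(b2),
            attrs_to_tokens(links$attrs[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature file
#' @param features data frame as returned by [read_feature_file()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_file <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(seq_len(nrow(features)), function(i) {
    paste(c(features$seq_id[i], fmt_bp(features$start[i]), fmt_bp(features$end[i]),
            attrs_to_tokens(features$attrs[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.genome_def <- function(x, ...) {
  cat(sprintf("<genome_def '%s': %d sequence(s), %s bp>\n", x$name,
              nrow(x$chroms),
              fmt_bp(sum(x$chroms$end - x$chroms$start + 1))))
  invisible(x)
}

#' @export
print.link_set <- function(x, ...) {
  n_inv <- sum(x$orientation == "inverted")
  cat(sprintf("<link_set: %d link(s), %d inverted>\n", nrow(x), n_inv))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x)[1:7], 10))
  invisible(x)
}
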