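# Shared internal helpers: line-based IO, tokenization, number formatting.

#' Read all lines of a plain or gzip-compressed text file
#'
#' `gzfile()` transparently handles uncompressed input, so every reader in the
#' package accepts both `.txt` and `.txt.gz`.
#' @noRd
read_text_lines <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("path must be a single non-empty string", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

# Split a line on any run of spaces/tabs; leading/trailing whitespace ignored.
split_ws <- function(line) {
  line <- trimws(line)
  if (!nzchar(line)) return(character(0))
  strsplit(line, "[ \t]+")[[1L]]
}

# TRUE for lines carrying data: non-blank and not a "#" comment.
is_data_line <- function(line) {
  s <- trimws(line)
  nzchar(s) && !startsWith(s, "#")
}

#' Parse an integer-valued coordinate token, with file/line context in errors
#' @noRd
parse_coord <- function(token, what, file = "<input>", lineno = NA_integer_) {
  v <- suppressWarnings(as.numeric(token))
  if (is.na(v) || !is.finite(v) || v != floor(v)) {
    stop(sprintf("%s, line %s: %s is not an integer coordinate: '%s'",
                 file, lineno, what, token), call. = FALSE)
  }
  v
}

# Fixed plain (never scientific) integer formatting for file writers.
fmt_bp <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, justify = "none")
}

# Fixed 3-decimal formatting used for every coordinate written into SVG.
# One formatting routine keeps output byte-identical across runs/platforms.
fmt3 <- function(x) sprintf("%.3f", x + 0)

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Minimal XML text escaping for SVG <text> payloads and attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}
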