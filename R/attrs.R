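# Attribute maps: the ordered key=value pairs carried by chromosomes, links,
# features and configuration blocks.

#' Construct an attribute map
#'
#' An attribute map is an ordered set of `key = value` string pairs. Keys are
#' case-insensitive and stored lower-cased; values are kept verbatim. Keys are
#' unique; order of first occurrence is preserved.
#'
#' @param keys character vector of keys (lower-cased on storage)
#' @param values character vector of values, same length as `keys`
#' @return an object of class `attr_map` (a named character vector)
#' @export
attr_map <- function(keys = character(0), values = character(0)) {
  stopifnot(length(keys) == length(values))
  keys <- tolower(as.character(keys))
  values <- as.character(values)
  out <- character(0)
  for (i in seq_along(keys)) {
    if (keys[i] %in% names(out)) {
      out[[keys[i]]] <- values[i]        # last wins, position kept
    } else {
      out <- c(out, stats::setNames(values[i], keys[i]))
    }
  }
  structure(out, class = "attr_map")
}

#' Parse optional `key=value` attribute tokens
#'
#' Tokens beyond the ordered coordinate columns of genome/link/feature files
#' are unordered `key=value` attributes (e.g. `fill=green`). Keys are folded to
#' lower case; on a duplicate key the last occurrence wins and a warning is
#' raised. A token without `=`, or with an empty key or value, is a format
#' error naming the file, line and token.
#'
#' @param tokens character vector of raw tokens
#' @param file,lineno context used in error/warning messages
#' @return an `attr_map`
#' @export
#' @examples
#' parse_attr_fields(c("fill=green"))
parse_attr_fields <- function(tokens, file = "<input>", lineno = NA_integer_) {
  out <- character(0)
  for (tok in tokens) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 1L) {
      stop(sprintf("%s, line %s: malformed attribute token '%s' (expected key=value)",
                   file, lineno, tok), call. = FALSE)
    }
    key <- tolower(substr(tok, 1L, eq - 1L))
    val <- substr(tok, eq + 1L, nchar(tok))
    if (!nzchar(key) || !nzchar(val)) {
      stop(sprintf("%s, line %s: malformed attribute token '%s' (empty key or value)",
                   file, lineno, tok), call. = FALSE)
    }
    if (key %in% names(out)) {
      warning(sprintf("%s, line %s: duplicate attribute key '%s'; last value wins",
                      file, lineno, key), call. = FALSE)
      out[[key]] <- val
    } else {
      out <- c(out, stats::setNames(val, key))
    }
  }
  structure(out, class = "attr_map")
}

#' Serialize an attribute map back to `key=value` tokens
#' @param attrs an `attr_map`
#' @return character vector, one `key=value` token per entry, original order
#' @export
attrs_to_tokens <- function(attrs) {
  if (is.null(attrs) || length(attrs) == 0L) return(character(0))
  paste0(names(attrs), "=", unname(unclass(attrs)))
}

# Lookup with default; returns a plain string or `default`.
attr_get <- function(attrs, key, default = NULL) {
  if (is.null(attrs) || length(attrs) == 0L) return(default)
  key <- tolower(key)
  if (key %in% names(attrs)) unname(unclass(attrs)[[key]]) else default
}

#' @export
print.attr_map <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<attr_map: empty>\n")
  } else {
    cat("<attr_map>", paste(attrs_to_tokens(x), collapse = " "), "\n")
  }
  invisible(x)
}
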