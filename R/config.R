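# Configuration file parsing and the SetParaFor parameter cascade.
#
# Syntax (fixed by this package; the envelope is documented in the vignette):
#   - "#" comments and blank lines are ignored everywhere.
#   - Top-level declarations, in file order:
#       Genome = <path>                genome (sequence length) file
#       Feature = <genome index> <path>   feature file attached to a genome
#       Link = <path> [<iA> <iB>]      link file joining two genomes; indices
#                                      default to (k, k+1) for the k-th link
#   - A line "SetParaFor = <scope>" opens a parameter block; following
#     key=value lines belong to it until the next declaration or block.
#     Scopes: global, GenomeALL, Genome<N>, Link<N> (case-insensitive).
#
# Cascade precedence (later overrides earlier, key by key):
#   built-in defaults < global < GenomeALL < GenomeN   (genomes)
#   built-in defaults < global < LinkN                 (link sets)
# with per-record file attributes overriding the resolved LinkParams for that
# record only. Within one scope, later blocks override earlier (file order).

new_scope_id <- function(kind, index = NA_integer_) {
  stopifnot(kind %in% c("global", "genome_all", "genome_n", "link_n"))
  structure(list(kind = kind, index = index), class = "scope_id")
}

parse_scope <- function(text, file = "<config>", lineno = NA_integer_) {
  t <- trimws(text)
  lt <- tolower(t)
  if (lt == "global") return(new_scope_id("global"))
  if (lt == "genomeall") return(new_scope_id("genome_all"))
  m <- regmatches(lt, regexec("^(genome|link)([0-9]+)$", lt))[[1L]]
  if (length(m) == 3L) {
    idx <- as.integer(m[3L])
    if (idx < 1L) {
      stop(sprintf("%s, line %s: scope index must be >= 1 in '%s'", file, lineno, t),
           call. = FALSE)
    }
    return(new_scope_id(if (m[2L] == "genome") "genome_n" else "link_n", idx))
  }
  stop(sprintf("%s, line %s: unknown SetParaFor scope '%s' (expected global, GenomeALL, Genome<N> or Link<N>)",
               file, lineno, t), call. = FALSE)
}

#' Parse a region specifier `seq:start:end`
#'
#' The form used by `ZoomRegion`, e.g. `"Chr6:12914310:18879240"`.
#'
#' @param text a single string `seq:start:end`
#' @return list with `seq_id`, `start`, `end` (class `region_spec`)
#' @export
#' @examples
#' parse_region("Chr6:12914310:18879240")
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) {
    stop(sprintf("malformed region '%s': expected seq:start:end", text), call. = FALSE)
  }
  s <- suppressWarnings(as.numeric(parts[2L]))
  e <- suppressWarnings(as.numeric(parts[3L]))
  if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
    stop(sprintf("malformed region '%s': start/end must be integers", text), call. = FALSE)
  }
  if (!nzchar(parts[1L])) {
    stop(sprintf("malformed region '%s': empty sequence ID", text), call. = FALSE)
  }
  if (s > e) {
    stop(sprintf("malformed region '%s': start > end", text), call. = FALSE)
  }
  structure(list(seq_id = parts[1L], start = s, end = e), class = "region_spec")
}

# ---- built-in defaults ------------------------------------------------------

#' Built-in default drawing parameters
#'
#' The bottom layer of the cascade. Canvas-level keys (`canvas_width`,
#' `slot_pitch`, `margin`) are only meaningful in the `global` scope.
#'
#' @return named list of defaults
#' @export
default_genome_params <- function() {
  list(
    move_to_x = NA_real_,       # canvas units; NA -> left margin
    move_to_y = NA_real_,       # canvas units; NA -> stacked slot
    rotate_chr = 0,             # degrees, counter-clockwise, about track origin
    zoom_chr = 1,               # >0, scales the whole track about its origin
    zoom_region = NULL,         # region_spec; restricts the track to one slice
    label_text = NA_character_, # NA -> genome name
    label_color = "black",
    label_position = "left",    # left | right | top | bottom
    show_label = TRUE,
    show_coordinates = FALSE,
    chr_height = 20,            # canvas units
    chr_spacing = 10,           # gap between chromosome rectangles
    spe_region_width_ratio = 1, # feature glyph height / chr_height
    rounded_ends = TRUE,        # rounded chromosome caps, radius chr_height/2
    fill = "#c6dbef",
    stroke = "#2171b5"
  )
}

#' @rdname default_genome_params
#' @export
default_link_params <- function() {
  list(
    style = 2L,                 # 1 straight quad; 2-5 Bezier ribbon profiles
    style_up_down = "DownUp",   # edge of genome A, edge of genome B
    height_ratio = 1,           # scales Bezier control-point offsets
    fill = "#bdbdbd",
    stroke = "none",
    opacity = 0.5
  )
}

#' @rdname default_genome_params
#' @export
default_global_params <- function() {
  list(canvas_width = 1200, slot_pitch = 120, margin = 60)
}

# canonical key lookup: config keys are matched case-insensitively with
# underscores ignored, so MoveToX == movetox == move_to_x.
canon_key <- function(key) gsub("_", "", tolower(key), fixed = TRUE)

# safe lookup in a named character map: NULL when absent
map_get <- function(map, key) {
  if (key %in% names(map)) map[[key]] else NULL
}

.genome_key_map <- local({
  fields <- names(default_genome_params())
  extra <- c(label = "label_text", showcoordinate = "show_coordinates",
             showticks = "show_coordinates")
  m <- stats::setNames(fields, canon_key(fields))
  c(m, extra)
})

.link_key_map <- local({
  fields <- names(default_link_params())
  extra <- c(linkstyle = "style", styleupdown = "style_up_down")
  m <- stats::setNames(fields, canon_key(fields))
  c(m, extra)
})

.global_key_map <- local({
  fields <- names(default_global_params())
  stats::setNames(fields, canon_key(fields))
})

.genome_numeric <- c("move_to_x", "move_to_y", "rotate_chr", "zoom_chr",
                     "chr_height", "chr_spacing", "spe_region_width_ratio")
.genome_bool <- c("show_label", "show_coordinates", "rounded_ends")
.link_numeric <- c("height_ratio", "opacity")

parse_bool <- function(value, key, where) {
  v <- tolower(trimws(value))
  if (v %in% c("1", "true", "yes", "on")) return(TRUE)
  if (v %in% c("0", "false", "no", "off")) return(FALSE)
  stop(sprintf("%s: key '%s' expects a boolean (1/0/true/false/yes/no), got '%s'",
               where, key, value), call. = FALSE)
}

parse_num <- function(value, key, where) {
  v <- suppressWarnings(as.numeric(value))
  if (is.na(v) || !is.finite(v)) {
    stop(sprintf("%s: key '%s' expects a number, got '%s'", where, key, value),
         call. = FALSE)
  }
  v
}

# ---- config model -----------------------------------------------------------

#' Parse a configuration file
#'
#' See the package vignette for the full syntax. Genome, feature and link
#' declarations are ordered top-level entries; `SetParaFor` blocks carry
#' scoped `key=value` parameters. Referenced data files are checked for
#' existence and block indices for dangling references; all such problems are
#' reported together. Unknown parameter keys are retained (with a warning)
#' for forward compatibility.
#'
#' @param path configuration file path
#' @param check_files if `TRUE` (default) verify that referenced data files
#'   exist at parse time
#' @return a `config_model`: list with `genomes` (each: `file`, `features`),
#'   `links` (each: `file`, `genome_a`, `genome_b`) and `blocks`
#'   (each: `scope`, `params` attr_map)
#' @export
parse_config <- function(path, check_files = TRUE) {
  lines <- read_text_lines(path)
  dir <- dirname(path)
  resolve_path <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
  }

  genomes <- list()
  links <- list()
  blocks <- list()
  cur_scope <- NULL
  cur_params_keys <- character(0)
  cur_params_vals <- character(0)
  errors <- character(0)

  flush_block <- function() {
    if (!is.null(cur_scope)) {
      blocks[[length(blocks) + 1L]] <<- list(
        scope = cur_scope,
        params = attr_map(cur_params_keys, cur_params_vals))
    }
    cur_scope <<- NULL
    cur_params_keys <<- character(0)
    cur_params_vals <<- character(0)
  }

  for (i in seq_along(lines)) {
    if (!is_data_line(lines[i])) next
    line <- trimws(lines[i])
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 1L) {
      errors <- c(errors, sprintf("line %d: expected key=value, got '%s'", i, line))
      next
    }
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    ck <- canon_key(key)
    if (ck == "genome") {
      flush_block()
      genomes[[length(genomes) + 1L]] <- list(file = resolve_path(val),
                                              features = character(0))
    } else if (ck == "feature") {
      flush_block()
      tok <- split_ws(val)
      if (length(tok) != 2L || is.na(suppressWarnings(as.integer(tok[1L])))) {
        errors <- c(errors, sprintf("line %d: Feature expects '<genome index> <path>'", i))
        next
      }
      gi <- as.integer(tok[1L])
      if (gi < 1L || gi > length(genomes)) {
        errors <- c(errors, sprintf("line %d: Feature refers to undeclared Genome%d", i, gi))
        next
      }
      genomes[[gi]]$features <- c(genomes[[gi]]$features, resolve_path(tok[2L]))
    } else if (ck == "link") {
      flush_block()
      tok <- split_ws(val)
      if (length(tok) == 1L) {
        k <- length(links) + 1L
        ga <- k; gb <- k + 1L
      } else if (length(tok) == 3L) {
        ga <- suppressWarnings(as.integer(tok[2L]))
        gb <- suppressWarnings(as.integer(tok[3L]))
        if (is.na(ga) || is.na(gb)) {
          errors <- c(errors, sprintf("line %d: Link genome indices must be integers", i))
          next
        }
      } else {
        errors <- c(errors, sprintf("line %d: Link expects '<path> [<iA> <iB>]'", i))
        next
      }
      links[[length(links) + 1L]] <- list(file = resolve_path(tok[1L]),
                                          genome_a = ga, genome_b = gb)
    } else if (ck == "setparafor") {
      flush_block()
      scope <- tryCatch(parse_scope(val, path, i), error = function(e) {
        errors <<- c(errors, conditionMessage(e)); NULL
      })
      cur_scope <- scope
      if (is.null(scope)) cur_scope <- new_scope_id("global")  # placeholder; error already queued
    } else {
      if (is.null(cur_scope)) {
        errors <- c(errors, sprintf(
          "line %d: parameter '%s' outside any SetParaFor block", i, key))
        next
      }
      cur_params_keys <- c(cur_params_keys, key)
      cur_params_vals <- c(cur_params_vals, val)
    }
  }
  flush_block()

  # dangling scope indices
  for (b in blocks) {
    sc <- b$scope
    if (sc$kind == "genome_n" && sc$index > length(genomes)) {
      errors <- c(errors, sprintf("SetParaFor=Genome%d refers to an undeclared genome (%d declared)",
                                  sc$index, length(genomes)))
    }
    if (sc$kind == "link_n" && sc$index > length(links)) {
      errors <- c(errors, sprintf("SetParaFor=Link%d refers to an undeclared link file (%d declared)",
                                  sc$index, length(links)))
    }
  }
  # link genome indices valid and distinct
  for (k in seq_along(links)) {
    l <- links[[k]]
    if (l$genome_a < 1L || l$genome_a > length(genomes) ||
        l$genome_b < 1L || l$genome_b > length(genomes)) {
      errors <- c(errors, sprintf("Link%d joins undeclared genome indices (%s, %s)",
                                  k, l$genome_a, l$genome_b))
    } else if (l$genome_a == l$genome_b) {
      errors <- c(errors, sprintf("Link%d joins a genome to itself (index %d)", k, l$genome_a))
    }
  }
  if (check_files) {
    for (g in genomes) {
      if (!file.exists(g$file)) errors <- c(errors, sprintf("genome file not found: %s", g$file))
      for (f in g$features) if (!file.exists(f)) errors <- c(errors, sprintf("feature file not found: %s", f))
    }
    for (l in links) {
      if (!file.exists(l$file)) errors <- c(errors, sprintf("link file not found: %s", l$file))
    }
  }
  if (length(errors) > 0L) {
    stop(sprintf("%s: %d configuration error(s):\n  - %s",
                 path, length(errors), paste(errors, collapse = "\n  - ")),
         call. = FALSE)
  }
  structure(list(genomes = genomes, links = links, blocks = blocks, path = path),
            class = "config_model")
}

# ---- cascade resolution -----------------------------------------------------

# scope rank: only rank and within-scope file order determine precedence
scope_rank_genome <- function(scope, genome_index) {
  if (scope$kind == "global") return(1L)
  if (scope$kind == "genome_all") return(2L)
  if (scope$kind == "genome_n" && scope$index == genome_index) return(3L)
  NA_integer_
}

scope_rank_link <- function(scope, link_index) {
  if (scope$kind == "global") return(1L)
  if (scope$kind == "link_n" && scope$index == link_index) return(2L)
  NA_integer_
}

apply_genome_kv <- function(params, key, value, where) {
  field <- map_get(.genome_key_map, canon_key(key))
  if (is.null(field)) {
    # canvas keys and link keys may legitimately sit in shared (global) scope
    if (!is.null(map_get(.global_key_map, canon_key(key))) ||
        !is.null(map_get(.link_key_map, canon_key(key)))) return(params)
    warning(sprintf("%s: unknown parameter '%s' retained without effect", where, key),
            call. = FALSE)
    params$extra[[canon_key(key)]] <- value
    return(params)
  }
  if (field %in% .genome_numeric) {
    v <- parse_num(value, key, where)
    if (field == "zoom_chr" && v <= 0) {
      stop(sprintf("%s: ZoomChr must be > 0, got %s", where, value), call. = FALSE)
    }
    if (field == "spe_region_width_ratio" && v <= 0) {
      stop(sprintf("%s: SpeRegionWidthRatio must be > 0, got %s", where, value), call. = FALSE)
    }
    if (field == "rotate_chr") v <- v %% 360
    params[[field]] <- v
  } else if (field %in% .genome_bool) {
    params[[field]] <- parse_bool(value, key, where)
  } else if (field == "zoom_region") {
    params[[field]] <- parse_region(value)
  } else if (field == "label_position") {
    v <- tolower(value)
    if (!v %in% c("left", "right", "top", "bottom")) {
      stop(sprintf("%s: LabelPosition must be left/right/top/bottom, got '%s'",
                   where, value), call. = FALSE)
    }
    params[[field]] <- v
  } else {
    params[[field]] <- value
  }
  params
}

apply_link_kv <- function(params, key, value, where) {
  field <- map_get(.link_key_map, canon_key(key))
  if (is.null(field)) {
    if (!is.null(map_get(.global_key_map, canon_key(key))) ||
        !is.null(map_get(.genome_key_map, canon_key(key)))) return(params)
    warning(sprintf("%s: unknown parameter '%s' retained without effect", where, key),
            call. = FALSE)
    params$extra[[canon_key(key)]] <- value
    return(params)
  }
  if (field == "style") {
    v <- parse_num(value, key, where)
    if (!(v %in% 1:5)) {
      stop(sprintf("%s: Style must be an integer in 1..5, got '%s'", where, value),
           call. = FALSE)
    }
    params[[field]] <- as.integer(v)
  } else if (field == "style_up_down") {
    v <- canon_style_up_down(value, where)
    params[[field]] <- v
  } else if (field %in% .link_numeric) {
    v <- parse_num(value, key, where)
    if (field == "height_ratio" && v <= 0) {
      stop(sprintf("%s: HeightRatio must be > 0, got %s", where, value), call. = FALSE)
    }
    if (field == "opacity" && (v < 0 || v > 1)) {
      stop(sprintf("%s: Opacity must be in [0,1], got %s", where, value), call. = FALSE)
    }
    params[[field]] <- v
  } else {
    params[[field]] <- value
  }
  params
}

canon_style_up_down <- function(value, where = "<attrs>") {
  v <- tolower(trimws(value))
  map <- c(upup = "UpUp", updown = "UpDown", downup = "DownUp", downdown = "DownDown")
  if (!v %in% names(map)) {
    stop(sprintf("%s: StyleUpDown must be one of UpUp/UpDown/DownUp/DownDown, got '%s'",
                 where, value), call. = FALSE)
  }
  unname(map[[v]])
}

scope_label <- function(scope) {
  switch(scope$kind,
         global = "SetParaFor=global",
         genome_all = "SetParaFor=GenomeALL",
         genome_n = sprintf("SetParaFor=Genome%d", scope$index),
         link_n = sprintf("SetParaFor=Link%d", scope$index))
}

#' Resolve effective drawing parameters for one genome
#'
#' Applies the cascade `defaults < global < GenomeALL < GenomeN`, later layers
#' overriding earlier key by key. Resolution is pure and depends only on
#' scope rank and within-scope file order.
#'
#' @param model a `config_model`
#' @param genome_index 1-based index of a declared genome
#' @return named list of effective genome parameters
#' @export
resolve_genome_params <- function(model, genome_index) {
  stopifnot(inherits(model, "config_model"))
  if (genome_index < 1L || genome_index > length(model$genomes)) {
    stop(sprintf("genome index %s not declared (%d genomes)", genome_index,
                 length(model$genomes)), call. = FALSE)
  }
  params <- default_genome_params()
  params$extra <- list()
  ranks <- vapply(model$blocks, function(b) scope_rank_genome(b$scope, genome_index), 0L)
  ord <- order(ranks, seq_along(ranks))   # stable: rank, then file order
  for (bi in ord) {
    if (is.na(ranks[bi])) next
    b <- model$blocks[[bi]]
    kv <- b$params
    for (k in names(kv)) {
      params <- apply_genome_kv(params, k, unclass(kv)[[k]], scope_label(b$scope))
    }
  }
  params
}

#' Resolve effective parameters for one link set
#'
#' Cascade `defaults < global < LinkN`. Per-record attributes from the link
#' file override the result for that record only; see
#' [effective_link_style()].
#'
#' @param model a `config_model`
#' @param link_index 1-based index of a declared link file
#' @return named list of effective link parameters
#' @export
resolve_link_params <- function(model, link_index) {
  stopifnot(inherits(model, "config_model"))
  if (link_index < 1L || link_index > length(model$links)) {
    stop(sprintf("link index %s not declared (%d link files)", link_index,
                 length(model$links)), call. = FALSE)
  }
  params <- default_link_params()
  params$extra <- list()
  ranks <- vapply(model$blocks, function(b) scope_rank_link(b$scope, link_index), 0L)
  ord <- order(ranks, seq_along(ranks))
  for (bi in ord) {
    if (is.na(ranks[bi])) next
    b <- model$blocks[[bi]]
    kv <- b$params
    for (k in names(kv)) {
      params <- apply_link_kv(params, k, unclass(kv)[[k]], scope_label(b$scope))
    }
  }
  params
}

#' Resolve canvas-level parameters from global blocks
#' @param model a `config_model`
#' @return list with `canvas_width`, `slot_pitch`, `margin`
#' @export
resolve_global_params <- function(model) {
  params <- default_global_params()
  for (b in model$blocks) {
    if (b$scope$kind != "global") next
    kv <- b$params
    for (k in names(kv)) {
      field <- map_get(.global_key_map, canon_key(k))
      if (is.null(field)) next
      params[[field]] <- parse_num(unclass(kv)[[k]], k, "SetParaFor=global")
    }
  }
  params
}

#' Apply per-record attribute overrides to resolved link parameters
#'
#' A record's `key=value` attributes (e.g. `fill=red`, `style=1`) override the
#' resolved link-set parameters for that record only.
#'
#' @param params resolved link parameters (from [resolve_link_params()])
#' @param attrs the record's `attr_map`
#' @return link parameters with overrides applied
#' @export
effective_link_style <- function(params, attrs) {
  if (is.null(attrs) || length(attrs) == 0L) return(params)
  for (k in names(attrs)) {
    if (!is.null(map_get(.link_key_map, canon_key(k)))) {
      params <- apply_link_kv(params, k, unclass(attrs)[[k]], "<record attrs>")
    }
  }
  params
}

#' Serialize fully resolved parameters for debugging
#'
#' Emits the effective parameters of every genome and link set in the same
#' `key=value` syntax the configuration file uses (the `--dump-config` CLI
#' action).
#'
#' @param model a `config_model`
#' @return character vector of lines
#' @export
dump_config <- function(model) {
  fmt_val <- function(v) {
    if (inherits(v, "region_spec")) return(sprintf("%s:%s:%s", v$seq_id, fmt_bp(v$start), fmt_bp(v$end)))
    if (is.logical(v)) return(if (v) "true" else "false")
    if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
    as.character(v)
  }
  out <- character(0)
  gp <- resolve_global_params(model)
  out <- c(out, "SetParaFor=global",
           vapply(names(gp), function(k) paste0(k, "=", fmt_val(gp[[k]])), ""))
  for (i in seq_along(model$genomes)) {
    p <- resolve_genome_params(model, i)
    p$extra <- NULL
    keep <- !vapply(p, is.null, TRUE)
    out <- c(out, "", sprintf("SetParaFor=Genome%d", i),
             vapply(names(p)[keep], function(k) paste0(k, "=", fmt_val(p[[k]])), ""))
  }
  for (i in seq_along(model$links)) {
    p <- resolve_link_params(model, i)
    p$extra <- NULL
    out <- c(out, "", sprintf("SetParaFor=Link%d", i),
             vapply(names(p), function(k) paste0(k, "=", fmt_val(p[[k]])), ""))
  }
  out
}

#' @export
print.config_model <- function(x, ...) {
  cat(sprintf("<config_model: %d genome(s), %d link file(s), %d parameter block(s)>\n",
              length(x$genomes), length(x$links), length(x$blocks)))
  invisible(x)
}
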