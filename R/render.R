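# Rendering: ribbon path geometry, axis ticks, feature glyphs, SVG
# serialization (deterministic, 3-decimal coordinates) and optional PNG
# rasterization.

# ---- ribbon geometry --------------------------------------------------------

#' Evaluate a cubic Bezier curve
#' @param t parameter(s) in `[0, 1]`
#' @param p0,p1,p2,p3 points `c(x, y)`
#' @return a 2-column matrix of points
#' @export
cubic_bezier <- function(t, p0, p1, p2, p3) {
  u <- 1 - t
  cbind(u^3 * p0[1L] + 3 * u^2 * t * p1[1L] + 3 * u * t^2 * p2[1L] + t^3 * p3[1L],
        u^3 * p0[2L] + 3 * u^2 * t * p1[2L] + 3 * u * t^2 * p2[2L] + t^3 * p3[2L])
}

# Vertical control-point offset profiles per style. The offsets are linear in
# height_ratio so every curved style degenerates to the straight quadrilateral
# as height_ratio -> 0. (fa, fb) are the fractions of
# height_ratio * default_height applied at the A and B anchors.
#   style 1: straight quadrilateral (no control points)
#   style 2: symmetric S-curve    fa = fb = 0.5, toward the partner genome
#   style 3: taut curve           fa = fb = 0.25, toward the partner genome
#   style 4: deep sag             fa = fb = 1.0, along each edge's outward
#            normal — with DownDown this yields the wrap-around ribbon
#   style 5: asymmetric curve     fa = 0.8, fb = 0.2, toward the partner
ribbon_style_profile <- function(style) {
  switch(as.character(style),
         `1` = NULL,
         `2` = c(0.5, 0.5),
         `3` = c(0.25, 0.25),
         `4` = c(1.0, 1.0),
         `5` = c(0.8, 0.2),
         stop(sprintf("link style must be an integer in 1..5, got %s", style),
              call. = FALSE))
}

#' Build the closed path of one link ribbon
#'
#' The region runs `a_start -> a_end -> b_end -> b_start -> close`. Style 1
#' joins the anchors with straight segments; styles 2-5 use cubic Bezier
#' cross-segments whose control points sit vertically offset from the anchors
#' by `f(style) * height_ratio * default_height` (profiles documented in
#' [ribbon_style_profile()]). Path endpoints equal the anchors exactly.
#'
#' @param anchors a `ribbon_anchors`
#' @param style integer 1..5
#' @param height_ratio positive scale on the control-point offsets
#' @param default_height reference height in canvas units (the inter-track
#'   slot pitch)
#' @param fill,stroke,opacity style attributes carried onto the primitive
#' @param id unique primitive id
#' @return a `ribbon_path` primitive: `kind = "path"`, `segments` (list of
#'   `M`/`L`/`C`/`Z` commands with point matrices), plus style fields
#' @export
build_ribbon_path <- function(anchors, style = 2, height_ratio = 1,
                              default_height = 100, fill = "#bdbdbd",
                              stroke = "none", opacity = 0.5,
                              id = "ribbon") {
  if (length(style) != 1L || is.na(style) || !(style %in% 1:5)) {
    stop(sprintf("link style must be an integer in 1..5, got %s",
                 paste(style, collapse = ",")), call. = FALSE)
  }
  a1 <- anchors$a_start; a2 <- anchors$a_end
  b1 <- anchors$b_start; b2 <- anchors$b_end
  segs <- list(list(cmd = "M", pts = rbind(a1)),
               list(cmd = "L", pts = rbind(a2)))
  if (style == 1) {
    segs <- c(segs, list(list(cmd = "L", pts = rbind(b2)),
                         list(cmd = "L", pts = rbind(b1)),
                         list(cmd = "Z", pts = rbind(a1))))
  } else {
    prof <- ribbon_style_profile(style)
    d <- height_ratio * default_height
    if (style == 4) {
      # outward normal of each selected edge ("top" edge points up = -y)
      dir_a <- if (identical(anchors$edge_a, "top")) -1 else 1
      dir_b <- if (identical(anchors$edge_b, "top")) -1 else 1
    } else {
      # toward the partner genome
      mid_a <- (a1[2L] + a2[2L]) / 2
      mid_b <- (b1[2L] + b2[2L]) / 2
      dir_a <- if (mid_b >= mid_a) 1 else -1
      dir_b <- -dir_a
    }
    off_a <- c(0, dir_a * prof[1L] * d)
    off_b <- c(0, dir_b * prof[2L] * d)
    segs <- c(segs,
              list(list(cmd = "C", pts = rbind(a2 + off_a, b2 + off_b, b2)),
                   list(cmd = "L", pts = rbind(b1)),
                   list(cmd = "C", pts = rbind(b1 + off_b, a1 + off_a, a1)),
                   list(cmd = "Z", pts = rbind(a1))))
  }
  list(kind = "path", id = id, segments = segs,
       fill = fill, stroke = stroke, opacity = opacity, transform = NULL)
}

# ---- axis ticks -------------------------------------------------------------

#' Choose a "nice" major tick step for a bp window
#'
#' Candidate steps are `1, 2, 5 x 10^k`; the chosen step is the largest one
#' placing between 3 and 8 major ticks (multiples of the step, position 0
#' excluded) inside the window. Degenerate windows too small for 3 ticks fall
#' back to the largest step giving at least one tick.
#'
#' @param win_start,win_end window bounds in bp
#' @return list: `step`, `positions` (bp), `unit` (`"bp"`, `"kb"` or `"Mb"`),
#'   `labels`
#' @export
nice_ticks <- function(win_start, win_end) {
  lo <- max(win_start, 1)
  candidates <- as.vector(outer(c(1, 2, 5), 10^(0:9)))
  count_for <- function(step) {
    hi <- floor(win_end / step)
    lo_i <- ceiling(lo / step)
    max(hi - lo_i + 1, 0)
  }
  counts <- vapply(candidates, count_for, 0)
  ok <- counts >= 3 & counts <= 8
  step <- if (any(ok)) max(candidates[ok]) else {
    some <- counts >= 1
    if (!any(some)) return(list(step = NA_real_, positions = numeric(0),
                                unit = "bp", labels = character(0)))
    max(candidates[some & counts <= 8])
  }
  positions <- seq(ceiling(lo / step) * step, floor(win_end / step) * step, by = step)
  unit <- if (step >= 1e6) "Mb" else if (step >= 1e3) "kb" else "bp"
  div <- c(bp = 1, kb = 1e3, Mb = 1e6)[[unit]]
  labels <- paste0(format(positions / div, scientific = FALSE, trim = TRUE,
                          drop0trailing = TRUE), " ", unit)
  list(step = step, positions = positions, unit = unit, labels = labels)
}

#' Build axis tick primitives for one chromosome rectangle
#'
#' When `show_coordinates` is `FALSE` no primitives are produced. Otherwise
#' major ticks at [nice_ticks()] positions are drawn above the rectangle's
#' top edge with unit-suffixed labels.
#'
#' @param rect one-row `rects` slice of a `genome_track`
#' @param show_coordinates logical
#' @param transform the track's `affine` (attached to each primitive)
#' @param tick_len tick mark length in canvas units
#' @param id_prefix prefix for the generated primitive ids
#' @return list of line/text primitives (possibly empty)
#' @export
build_axis_ticks <- function(rect, show_coordinates, transform = affine_identity(),
                             tick_len = 5, id_prefix = "axis") {
  if (!isTRUE(show_coordinates)) return(list())
  nt <- nice_ticks(rect$win_start, rect$win_end)
  if (length(nt$positions) == 0L) return(list())
  span <- rect$win_end - rect$win_start
  out <- vector("list", 2L * length(nt$positions))
  for (j in seq_along(nt$positions)) {
    frac <- if (span == 0) 0.5 else (nt$positions[j] - rect$win_start) / span
    x <- rect$x0 + frac * (rect$x1 - rect$x0)
    out[[2L * j - 1L]] <- list(kind = "line", id = sprintf("%s-tick-%d", id_prefix, j),
                               x1 = x, y1 = rect$y0, x2 = x, y2 = rect$y0 - tick_len,
                               stroke = "black", transform = transform)
    out[[2L * j]] <- list(kind = "text", id = sprintf("%s-lab-%d", id_prefix, j),
                          x = x, y = rect$y0 - tick_len - 2, text = nt$labels[j],
                          anchor = "middle", fill = "black", font_size = 8,
                          transform = transform)
  }
  out
}

# ---- feature glyphs ---------------------------------------------------------

# default fill per feature type; any record-level fill attribute wins
feature_palette <- c(CDS = "#e41a1c", UTR = "#377eb8", TE = "#4daf4a",
                     SNP = "#984ea3", OTHER = "#ff7f00")

#' Build the glyph of one highlighted feature region
#'
#' A rectangle spanning the feature's bp range on its chromosome, with height
#' `chr_height * spe_region_width_ratio`, vertically centered on the
#' chromosome rectangle (a ratio above 1 overhangs both edges equally).
#' Feature-type default colors (CDS, UTR, TE, SNP) apply unless the record
#' sets its own `fill`/`stroke`.
#'
#' @param feature one-row feature slice (`seq_id`, `start`, `end`, `attrs`),
#'   already clipped to the window
#' @param rect the chromosome's one-row `rects` slice
#' @param params resolved genome parameters
#' @param transform the track's `affine`
#' @param id unique primitive id
#' @return a rect primitive
#' @export
build_feature_glyph <- function(feature, rect, params, transform = affine_identity(),
                                id = "feature") {
  span <- rect$win_end - rect$win_start
  f0 <- if (span == 0) 0.5 else (feature$start - rect$win_start) / span
  f1 <- if (span == 0) 0.5 else (feature$end - rect$win_start) / span
  x0 <- rect$x0 + f0 * (rect$x1 - rect$x0)
  x1 <- rect$x0 + f1 * (rect$x1 - rect$x0)
  ratio <- params$spe_region_width_ratio %||% 1
  h <- rect$height * ratio
  y0 <- rect$y0 + (rect$height - h) / 2
  a <- feature$attrs[[1L]]
  ftype <- toupper(attr_get(a, "feature", "OTHER"))
  def_fill <- if (ftype %in% names(feature_palette)) feature_palette[[ftype]] else feature_palette[["OTHER"]]
  list(kind = "rect", id = id,
       x = x0, y = y0, width = max(x1 - x0, 0.5), height = h, rx = 0,
       fill = attr_get(a, "fill", def_fill),
       stroke = attr_get(a, "stroke", "none"),
       transform = transform)
}

# ---- SVG serialization ------------------------------------------------------

svg_transform_attr <- function(T) {
  if (is.null(T)) return("")
  if (abs(T$a - 1) < 1e-12 && abs(T$b) < 1e-12 && abs(T$c) < 1e-12 &&
      abs(T$d - 1) < 1e-12 && abs(T$e) < 1e-12 && abs(T$f) < 1e-12) return("")
  sprintf(' transform="matrix(%s %s %s %s %s %s)"',
          fmt3(T$a), fmt3(T$b), fmt3(T$c), fmt3(T$d), fmt3(T$e), fmt3(T$f))
}

path_d <- function(segments) {
  parts <- vapply(segments, function(s) {
    if (s$cmd == "Z") return("Z")
    coords <- apply(s$pts, 1L, function(p) paste(fmt3(p[1L]), fmt3(p[2L])))
    paste(s$cmd, paste(coords, collapse = " "))
  }, "")
  paste(parts, collapse = " ")
}

emit_primitive <- function(p) {
  tr <- svg_transform_attr(p$transform)
  switch(p$kind,
    rect = sprintf('<rect id="%s" x="%s" y="%s" width="%s" height="%s" rx="%s" fill="%s" stroke="%s"%s/>',
                   xml_escape(p$id), fmt3(p$x), fmt3(p$y), fmt3(p$width), fmt3(p$height),
                   fmt3(p$rx %||% 0), xml_escape(p$fill), xml_escape(p$stroke), tr),
    path = sprintf('<path id="%s" d="%s" fill="%s" stroke="%s" fill-opacity="%s"%s/>',
                   xml_escape(p$id), path_d(p$segments), xml_escape(p$fill),
                   xml_escape(p$stroke), fmt3(p$opacity %||% 1), tr),
    line = sprintf('<line id="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"%s/>',
                   xml_escape(p$id), fmt3(p$x1), fmt3(p$y1), fmt3(p$x2), fmt3(p$y2),
                   xml_escape(p$stroke), tr),
    text = sprintf('<text id="%s" x="%s" y="%s" text-anchor="%s" font-family="Helvetica, Arial, sans-serif" font-size="%s" fill="%s"%s>%s</text>',
                   xml_escape(p$id), fmt3(p$x), fmt3(p$y), p$anchor %||% "middle",
                   fmt3(p$font_size %||% 12), xml_escape(p$fill %||% "black"), tr,
                   xml_escape(p$text)),
    stop(sprintf("unknown primitive kind '%s'", p$kind), call. = FALSE))
}

#' Serialize a scene to SVG 1.1 text
#'
#' Layers are emitted in fixed order (ribbons, chromosome rectangles,
#' features, axes, labels) inside `<g>` groups. All coordinates are printed
#' at 3 decimal places, so identical scenes yield byte-identical output.
#'
#' @param scene a `syn_scene`
#' @return a single string: the SVG document
#' @export
render_svg <- function(scene) {
  stopifnot(inherits(scene, "syn_scene"))
  ids <- unlist(lapply(unlist(scene$layers, recursive = FALSE), `[[`, "id"))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate primitive id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt3(scene$width), fmt3(scene$height), fmt3(scene$width), fmt3(scene$height)))
  for (layer in c("ribbons", "tracks", "features", "axes", "labels")) {
    prims <- scene$layers[[layer]]
    if (length(prims) == 0L) next
    out <- c(out, sprintf('<g id="layer-%s">', layer),
             vapply(prims, emit_primitive, ""), "</g>")
  }
  out <- c(out, "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a scene to an SVG file
#' @param scene a `syn_scene`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_svg <- function(scene, path) {
  svg <- render_svg(scene)
  con <- file(path, open = "wb")   # binary mode: byte-identical across platforms
  on.exit(close(con), add = TRUE)
  writeChar(svg, con, eos = NULL)
  invisible(path)
}

# ---- PNG rasterization ------------------------------------------------------

png_backend <- function() {
  if (requireNamespace("rsvg", quietly = TRUE)) return("rsvg")
  conv <- Sys.which("rsvg-convert")
  if (nzchar(conv)) return("rsvg-convert")
  cs <- Sys.which("cairosvg")
  if (nzchar(cs)) return("cairosvg")
  NA_character_
}

#' Is a PNG rasterization backend available?
#' @return logical
#' @export
has_png_backend <- function() !is.na(png_backend())

#' Rasterize SVG text to a PNG file
#'
#' Pixel dimensions are the canvas size times `dpi / 96`. Rasterization is
#' delegated to the first available backend (the `rsvg` package, a
#' `rsvg-convert` binary, or a `cairosvg` binary); when none is present a
#' clear error is raised — the SVG output is unaffected.
#'
#' @param svg_text SVG document text
#' @param path output PNG path
#' @param dpi raster resolution (96 reproduces canvas units as pixels)
#' @return `path`, invisibly
#' @export
rasterize_png <- function(svg_text, path, dpi = 96) {
  backend <- png_backend()
  if (is.na(backend)) {
    stop(paste("no PNG rasterization backend available (need the 'rsvg' R package,",
               "an 'rsvg-convert' binary or a 'cairosvg' binary); the SVG output",
               "is still produced"), call. = FALSE)
  }
  m <- regmatches(svg_text, regexec('width="([0-9.]+)" height="([0-9.]+)"', svg_text))[[1L]]
  if (length(m) != 3L) stop("cannot read canvas size from SVG text", call. = FALSE)
  w_px <- round(as.numeric(m[2L]) * dpi / 96)
  h_px <- round(as.numeric(m[3L]) * dpi / 96)
  if (backend == "rsvg") {
    rsvg::rsvg_png(charToRaw(svg_text), file = path, width = w_px, height = h_px)
  } else {
    tmp <- tempfile(fileext = ".svg")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(svg_text, tmp)
    args <- if (backend == "rsvg-convert") {
      c("-w", w_px, "-h", h_px, "-o", path, tmp)
    } else {
      c(tmp, "-o", path, "--output-width", w_px, "--output-height", h_px)
    }
    status <- system2(backend, as.character(args), stdout = FALSE, stderr = TRUE)
    if (!identical(attr(status, "status"), NULL) || !file.exists(path)) {
      stop(sprintf("PNG backend '%s' failed: %s", backend,
                   paste(status, collapse = "; ")), call. = FALSE)
    }
  }
  invisible(path)
}
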