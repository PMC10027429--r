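# Canvas geometry: affine transforms, chromosome rectangles, bp -> canvas
# mapping, zoom clipping, ribbon anchors and scene assembly.
#
# Conventions: canvas y grows downward (SVG). "Up" always means the top edge
# of a genome's rectangles (smaller y, pre-transform), "Down" the bottom edge.
# Each track's transform is translation(move_to_x, move_to_y) o
# rotation(rotate_chr, counter-clockwise, about the track origin) o
# scale(zoom_chr); the origin is the left end of the first chromosome
# baseline, which is local coordinate (0, 0).

# ---- affine transforms ------------------------------------------------------

#' Affine transforms on the canvas
#'
#' A 2x3 matrix `(a, b, c, d, e, f)` mapping `(x, y)` to
#' `(a x + c y + e, b x + d y + f)` — the same coefficient convention as SVG's
#' `matrix(a b c d e f)`.
#'
#' @param a,b,c,d,e,f coefficients
#' @return an `affine` object
#' @export
affine <- function(a = 1, b = 0, c = 0, d = 1, e = 0, f = 0) {
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f), class = "affine")
}

#' @rdname affine
#' @export
affine_identity <- function() affine()

#' @rdname affine
#' @param tx,ty translation in canvas units
#' @export
affine_translate <- function(tx, ty) affine(e = tx, f = ty)

#' @rdname affine
#' @param degrees rotation angle, counter-clockwise, in degrees. With y
#'   growing downward a counter-clockwise rotation has matrix
#'   `(cos t, -sin t, sin t, cos t)`.
#' @export
affine_rotate <- function(degrees) {
  t <- degrees * pi / 180
  affine(a = cos(t), b = -sin(t), c = sin(t), d = cos(t))
}

#' @rdname affine
#' @param s uniform scale factor
#' @export
affine_scale <- function(s) affine(a = s, d = s)

#' Compose two transforms: `affine_compose(A, B)` applies `B` first, then `A`
#' @param A,B `affine` objects
#' @return the composed `affine`
#' @export
affine_compose <- function(A, B) {
  affine(a = A$a * B$a + A$c * B$b,
         b = A$b * B$a + A$d * B$b,
         c = A$a * B$c + A$c * B$d,
         d = A$b * B$c + A$d * B$d,
         e = A$a * B$e + A$c * B$f + A$e,
         f = A$b * B$e + A$d * B$f + A$f)
}

#' Apply a transform to points
#' @param T an `affine`
#' @param xy numeric vector `c(x, y)` or a 2-column matrix of points
#' @return transformed points, same shape
#' @export
affine_apply <- function(T, xy) {
  if (is.matrix(xy)) {
    out <- cbind(T$a * xy[, 1L] + T$c * xy[, 2L] + T$e,
                 T$b * xy[, 1L] + T$d * xy[, 2L] + T$f)
    dimnames(out) <- NULL
    out
  } else {
    unname(c(T$a * xy[1L] + T$c * xy[2L] + T$e,
             T$b * xy[1L] + T$d * xy[2L] + T$f))
  }
}

affine_det <- function(T) T$a * T$d - T$b * T$c

track_transform <- function(params, default_slot_y, default_x = 60) {
  tx <- params$move_to_x %||% default_x
  ty <- params$move_to_y %||% default_slot_y
  T <- affine_compose(affine_translate(tx, ty),
                      affine_compose(affine_rotate(params$rotate_chr %||% 0),
                                     affine_scale(params$zoom_chr %||% 1)))
  if (abs(affine_det(T)) < 1e-12) {
    stop("degenerate track transform (determinant ~ 0)", call. = FALSE)
  }
  T
}

# ---- tracks -----------------------------------------------------------------

#' Build the canvas geometry of one genome track
#'
#' Chromosomes are laid on a horizontal baseline in file order, left to
#' right, separated by `chr_spacing` gaps, with a uniform bp-to-x scale of
#' `base_scale` canvas units per bp. If `zoom_region` is set, only that
#' chromosome slice is placed (the track reduces to the requested window).
#' The track transform is built from the resolved parameters;
#' `default_slot_y` supplies the vertical slot when `MoveToY` is unset
#' (genomes stack top-to-bottom in declaration order).
#'
#' @param genome a `genome_def`
#' @param params resolved genome parameters ([resolve_genome_params()])
#' @param default_slot_y baseline y used when `move_to_y` is `NA`
#' @param base_scale canvas units per bp (before `zoom_chr`)
#' @param default_x baseline x used when `move_to_x` is `NA`
#' @param genome_index index recorded on the track
#' @return a `genome_track`: `rects` data frame (`seq_id`, `x0`, `x1`, `y0`,
#'   `height`, `win_start`, `win_end`), `transform`, `params`
#' @export
build_track <- function(genome, params, default_slot_y, base_scale = 1e-5,
                        default_x = 60, genome_index = NA_integer_) {
  stopifnot(inherits(genome, "genome_def"))
  ch <- genome$chroms
  if (nrow(ch) == 0L) stop("cannot lay out an empty genome", call. = FALSE)

  zr <- params$zoom_region
  if (!is.null(zr)) {
    hit <- which(ch$seq_id == zr$seq_id)
    if (length(hit) == 0L) {
      stop(sprintf("zoom region sequence '%s' absent from genome '%s'",
                   zr$seq_id, genome$name), call. = FALSE)
    }
    ws <- max(zr$start, ch$start[hit])
    we <- min(zr$end, ch$end[hit])
    if (ws > we) {
      stop(sprintf("zoom region %s:%s:%s does not overlap sequence bounds",
                   zr$seq_id, fmt_bp(zr$start), fmt_bp(zr$end)), call. = FALSE)
    }
    ch <- ch[hit, , drop = FALSE]
    win_start <- ws; win_end <- we
  } else {
    win_start <- ch$start; win_end <- ch$end
  }

  spacing <- params$chr_spacing %||% 10
  height <- params$chr_height %||% 20
  widths <- pmax((win_end - win_start) * base_scale, 1e-9)
  x0 <- cumsum(c(0, utils::head(widths, -1) + spacing))
  rects <- data.frame(seq_id = ch$seq_id,
                      x0 = x0, x1 = x0 + widths,
                      y0 = 0, height = height,
                      win_start = win_start, win_end = win_end,
                      stringsAsFactors = FALSE)
  rects$chrom_attrs <- ch$attrs

  structure(list(genome_index = genome_index,
                 genome_name = genome$name,
                 rects = rects,
                 transform = track_transform(params, default_slot_y, default_x),
                 base_scale = base_scale,
                 params = params),
            class = "genome_track")
}

track_rect <- function(track, seq_id) {
  i <- match(seq_id, track$rects$seq_id)
  if (is.na(i)) {
    stop(sprintf("sequence '%s' not in track '%s'", seq_id, track$genome_name),
         call. = FALSE)
  }
  track$rects[i, , drop = FALSE]
}

#' Map a base-pair position to a canvas point
#'
#' Affine in `pos`: the window start maps to the rectangle's left edge and
#' the window end to its right edge; the result is already transformed by the
#' track transform. Positions outside the rendered window are an error
#' (callers clip first); positions exactly on the window boundary are fine.
#'
#' @param track a `genome_track`
#' @param seq_id sequence ID within the track
#' @param pos base-pair position(s); vectorized
#' @param edge `"top"`, `"bottom"` or `"mid"`: which horizontal edge of the
#'   chromosome rectangle supplies the y coordinate
#' @return for scalar `pos` a length-2 `c(x, y)`; otherwise a 2-column matrix
#' @export
bp_to_canvas <- function(track, seq_id, pos, edge = "mid") {
  r <- track_rect(track, seq_id)
  if (any(pos < r$win_start | pos > r$win_end)) {
    stop(sprintf("position outside rendered window %s:%s-%s (clip first)",
                 seq_id, fmt_bp(r$win_start), fmt_bp(r$win_end)), call. = FALSE)
  }
  span <- r$win_end - r$win_start
  frac <- if (span == 0) rep(0.5, length(pos)) else (pos - r$win_start) / span
  x <- r$x0 + frac * (r$x1 - r$x0)
  y <- switch(edge,
              top = r$y0,
              bottom = r$y0 + r$height,
              mid = r$y0 + r$height / 2,
              stop(sprintf("unknown edge '%s'", edge), call. = FALSE))
  pts <- cbind(unname(x), rep(y, length(x)))
  dimnames(pts) <- NULL
  out <- affine_apply(track$transform, pts)
  if (length(pos) == 1L) c(out[1L, 1L], out[1L, 2L]) else out
}

# ---- clipping ---------------------------------------------------------------

# map a sub-interval of (s, e) given fractions u0 <= u1 onto the partner
# interval (ps, pe); inverted orientation mirrors the fractions.
partner_slice <- function(ps, pe, u0, u1, inverted) {
  if (inverted) { tmp <- u0; u0 <- 1 - u1; u1 <- 1 - tmp }
  c(ps + u0 * (pe - ps), ps + u1 * (pe - ps))
}

clip_one_side <- function(s, e, ws, we) {
  cs <- max(s, ws); ce <- min(e, we)
  if (cs > ce) return(NULL)
  len <- e - s
  u0 <- if (len == 0) 0 else (cs - s) / len
  u1 <- if (len == 0) 1 else (ce - s) / len
  list(start = cs, end = ce, u0 = u0, u1 = u1)
}

#' Clip links to the rendered windows of two tracks
#'
#' Links wholly outside either track's window (or referencing sequences not
#' rendered) are dropped. A link partially overlapping a window is clipped to
#' it, and the partner interval is rescaled by the same fractions on the
#' matching ends (mirrored for inverted links). Kept/clipped/dropped counts
#' are returned alongside the records.
#'
#' @param links a `link_set` whose A side refers to `track_a`, B to `track_b`
#' @param track_a,track_b `genome_track`s
#' @return list with `links` (clipped `link_set` of kept records), `dropped`
#'   (logical flag per input record) and `counts`
#'   (`total`, `kept`, `clipped`, `dropped`)
#' @export
clip_links_to_windows <- function(links, track_a, track_b) {
  n <- nrow(links)
  dropped <- logical(n)
  clipped <- logical(n)
  out_rows <- vector("list", n)
  for (i in seq_len(n)) {
    ra_i <- match(links$seq_a[i], track_a$rects$seq_id)
    rb_i <- match(links$seq_b[i], track_b$rects$seq_id)
    if (is.na(ra_i) || is.na(rb_i)) { dropped[i] <- TRUE; next }
    ra <- track_a$rects[ra_i, ]; rb <- track_b$rects[rb_i, ]
    inv <- identical(links$orientation[i], "inverted")

    a <- clip_one_side(links$start_a[i], links$end_a[i], ra$win_start, ra$win_end)
    if (is.null(a)) { dropped[i] <- TRUE; next }
    b0 <- partner_slice(links$start_b[i], links$end_b[i], a$u0, a$u1, inv)
    b <- clip_one_side(min(b0), max(b0), rb$win_start, rb$win_end)
    if (is.null(b)) { dropped[i] <- TRUE; next }
    # clipping B may cut further; push the cut back onto A (mirrored if inverted)
    a2 <- partner_slice(a$start, a$end, b$u0, b$u1, inv)
    a_fin <- c(min(a2), max(a2))

    was_clipped <- a$start != links$start_a[i] || a$end != links$end_a[i] ||
      b$start != links$start_b[i] || b$end != links$end_b[i]
    clipped[i] <- was_clipped
    out_rows[[i]] <- list(seq_a = links$seq_a[i], start_a = a_fin[1L], end_a = a_fin[2L],
                          seq_b = links$seq_b[i], start_b = b$start, end_b = b$end,
                          orientation = links$orientation[i],
                          attrs = links$attrs[[i]])
  }
  kept_rows <- out_rows[!dropped]
  list(links = link_rows_to_set(kept_rows),
       dropped = dropped,
       counts = list(total = n,
                     kept = sum(!dropped),
                     clipped = sum(clipped & !dropped),
                     dropped = sum(dropped)))
}

# ---- ribbon anchors ---------------------------------------------------------

#' Compute the four canvas anchor points of one link ribbon
#'
#' The edge used on each genome comes from `style_up_down`: the first token
#' selects genome A's edge, the second genome B's ("Up" = top edge, "Down" =
#' bottom edge, regardless of the genomes' relative positions). Anchor x
#' positions are the [bp_to_canvas()] images of the interval endpoints. For
#' an inverted link the B anchors are swapped, so the ribbon self-crosses.
#'
#' @param link one-row slice of a clipped `link_set` (or a list with the same
#'   fields)
#' @param track_a,track_b `genome_track`s
#' @param link_params resolved link parameters (after per-record overrides)
#' @return a `ribbon_anchors` list: `a_start`, `a_end`, `b_start`, `b_end`
#'   (each `c(x, y)`), `edge_a`, `edge_b`
#' @export
compute_ribbon_anchors <- function(link, track_a, track_b, link_params) {
  sud <- link_params$style_up_down %||% "DownUp"
  edge_a <- if (startsWith(sud, "Up")) "top" else "bottom"
  edge_b <- if (endsWith(sud, "Up")) "top" else "bottom"
  a_start <- bp_to_canvas(track_a, link$seq_a, link$start_a, edge_a)
  a_end <- bp_to_canvas(track_a, link$seq_a, link$end_a, edge_a)
  b1 <- bp_to_canvas(track_b, link$seq_b, link$start_b, edge_b)
  b2 <- bp_to_canvas(track_b, link$seq_b, link$end_b, edge_b)
  if (identical(link$orientation, "inverted")) {
    b_start <- b2; b_end <- b1
  } else {
    b_start <- b1; b_end <- b2
  }
  structure(list(a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end,
                 edge_a = edge_a, edge_b = edge_b),
            class = "ribbon_anchors")
}

# ---- scene assembly ---------------------------------------------------------

#' Load every data file referenced by a configuration
#' @param model a `config_model`
#' @return list with `genomes` (list of `genome_def`), `features` (list of
#'   feature data frames per genome, concatenated), `links` (list of
#'   `link_set` per link entry)
#' @export
load_config_data <- function(model) {
  genomes <- vector("list", length(model$genomes))
  features <- vector("list", length(model$genomes))
  for (i in seq_along(model$genomes)) {
    g <- model$genomes[[i]]
    genomes[[i]] <- read_genome_file(g$file)
    feats <- lapply(g$features, read_feature_file)
    features[i] <- list(if (length(feats) > 0L) do.call(rbind, feats) else NULL)
  }
  links <- lapply(model$links, function(l) read_link_file(l$file))
  list(genomes = genomes, features = features, links = links)
}

#' Lay out the full scene
#'
#' Builds one track per genome (stacked top-to-bottom in declaration order,
#' one slot per genome, `MoveToY` overriding the slot) and assembles the
#' layered scene: (1) link ribbons, (2) chromosome rectangles, (3) feature
#' glyphs, (4) axis ticks, (5) labels. Every primitive carries resolved style
#' attributes and a unique deterministic id; ordering follows declaration
#' order, then file order. The bp-to-x scale is shared by all tracks so that
#' genome extents are comparable, sized so the widest genome fills the canvas
#' between margins.
#'
#' @param model a `config_model`
#' @param data parsed inputs from [load_config_data()] (loaded on demand when
#'   `NULL`)
#' @return a `syn_scene`: `width`, `height`, ordered `layers`, `tracks`,
#'   `counts`
#' @export
layout_scene <- function(model, data = NULL) {
  stopifnot(inherits(model, "config_model"))
  if (is.null(data)) data <- load_config_data(model)
  n_g <- length(model$genomes)
  if (n_g == 0L) stop("configuration declares no genomes", call. = FALSE)
  gp <- resolve_global_params(model)
  gparams <- lapply(seq_len(n_g), function(i) resolve_genome_params(model, i))

  # shared bp->x scale: widest genome (its rendered windows + gaps) spans the
  # canvas between margins
  plot_w <- gp$canvas_width - 2 * gp$margin
  scale_for <- function(i) {
    p <- gparams[[i]]
    ch <- data$genomes[[i]]$chroms
    if (!is.null(p$zoom_region)) {
      zr <- p$zoom_region
      hit <- which(ch$seq_id == zr$seq_id)
      if (length(hit) == 0L) return(Inf)
      span <- min(zr$end, ch$end[hit]) - max(zr$start, ch$start[hit])
      n_rect <- 1L
    } else {
      span <- sum(ch$end - ch$start)
      n_rect <- nrow(ch)
    }
    gaps <- (n_rect - 1L) * (p$chr_spacing %||% 10)
    if (span <= 0) return(Inf)
    max((plot_w - gaps), plot_w * 0.1) / span
  }
  base_scale <- min(vapply(seq_len(n_g), scale_for, 0))
  if (!is.finite(base_scale) || base_scale <= 0) {
    stop("cannot establish a bp-to-canvas scale (empty genomes?)", call. = FALSE)
  }

  slot_y <- gp$margin + (seq_len(n_g) - 1L) * gp$slot_pitch
  max_h <- max(vapply(gparams, function(p) p$chr_height %||% 20, 0))
  height <- gp$margin + (n_g - 1L) * gp$slot_pitch + max_h + gp$margin

  tracks <- lapply(seq_len(n_g), function(i) {
    build_track(data$genomes[[i]], gparams[[i]], slot_y[i],
                base_scale = base_scale, default_x = gp$margin,
                genome_index = i)
  })

  layers <- list(ribbons = list(), tracks = list(), features = list(),
                 axes = list(), labels = list())
  counts <- list(genomes = n_g,
                 chromosomes = sum(vapply(tracks, function(t) nrow(t$rects), 0L)),
                 links_total = 0L, links_kept = 0L, links_clipped = 0L,
                 links_dropped = 0L, features = 0L)

  # (1) ribbons
  for (k in seq_along(model$links)) {
    le <- model$links[[k]]
    lp <- resolve_link_params(model, k)
    ta <- tracks[[le$genome_a]]; tb <- tracks[[le$genome_b]]
    cl <- clip_links_to_windows(data$links[[k]], ta, tb)
    counts$links_total <- counts$links_total + cl$counts$total
    counts$links_kept <- counts$links_kept + cl$counts$kept
    counts$links_clipped <- counts$links_clipped + cl$counts$clipped
    counts$links_dropped <- counts$links_dropped + cl$counts$dropped
    lk <- cl$links
    for (r in seq_len(nrow(lk))) {
      rec <- lapply(lk, `[[`, r)   # row as list (attrs list-col included)
      rp <- effective_link_style(lp, rec$attrs)
      anchors <- compute_ribbon_anchors(rec, ta, tb, rp)
      layers$ribbons[[length(layers$ribbons) + 1L]] <- build_ribbon_path(
        anchors, style = rp$style, height_ratio = rp$height_ratio,
        default_height = gp$slot_pitch,
        fill = rp$fill, stroke = rp$stroke, opacity = rp$opacity,
        id = sprintf("ribbon-%d-%d", k, r))
    }
  }

  # (2) chromosome rects, (3) features, (4) axes, (5) labels
  for (i in seq_len(n_g)) {
    tr <- tracks[[i]]
    p <- gparams[[i]]
    tf <- tr$transform
    for (r in seq_len(nrow(tr$rects))) {
      rect <- tr$rects[r, ]
      ca <- rect$chrom_attrs[[1L]]
      layers$tracks[[length(layers$tracks) + 1L]] <- list(
        kind = "rect", id = sprintf("chr-%d-%s", i, rect$seq_id),
        x = rect$x0, y = rect$y0,
        width = rect$x1 - rect$x0, height = rect$height,
        rx = if (isTRUE(p$rounded_ends)) rect$height / 2 else 0,
        fill = attr_get(ca, "fill", p$fill),
        stroke = attr_get(ca, "stroke", p$stroke),
        transform = tf)
    }
    feats <- data$features[[i]]
    if (!is.null(feats) && nrow(feats) > 0L) {
      fidx <- 0L
      for (r in seq_len(nrow(feats))) {
        ri <- match(feats$seq_id[r], tr$rects$seq_id)
        if (is.na(ri)) next
        rect <- tr$rects[ri, ]
        fs <- max(feats$start[r], rect$win_start)
        fe <- min(feats$end[r], rect$win_end)
        if (fs > fe) next
        fidx <- fidx + 1L
        frow <- feats[r, ]; frow$start <- fs; frow$end <- fe
        layers$features[[length(layers$features) + 1L]] <- build_feature_glyph(
          frow, rect, p, transform = tf, id = sprintf("feature-%d-%d", i, fidx))
        counts$features <- counts$features + 1L
      }
    }
    if (isTRUE(p$show_coordinates)) {
      for (r in seq_len(nrow(tr$rects))) {
        ticks <- build_axis_ticks(tr$rects[r, ], show_coordinates = TRUE,
                                  transform = tf,
                                  id_prefix = sprintf("axis-%d-%s", i, tr$rects$seq_id[r]))
        layers$axes <- c(layers$axes, ticks)
      }
    }
    if (isTRUE(p$show_label)) {
      lab <- if (is.na(p$label_text)) tr$genome_name else p$label_text
      first <- tr$rects[1L, ]; last <- tr$rects[nrow(tr$rects), ]
      pos <- switch(p$label_position,
                    left = list(x = first$x0 - 10, y = first$y0 + first$height / 2, anchor = "end"),
                    right = list(x = last$x1 + 10, y = last$y0 + last$height / 2, anchor = "start"),
                    top = list(x = (first$x0 + last$x1) / 2, y = first$y0 - 8, anchor = "middle"),
                    bottom = list(x = (first$x0 + last$x1) / 2,
                                  y = first$y0 + first$height + 16, anchor = "middle"))
      layers$labels[[length(layers$labels) + 1L]] <- list(
        kind = "text", id = sprintf("label-%d", i),
        x = pos$x, y = pos$y, text = lab, anchor = pos$anchor,
        fill = p$label_color, font_size = 13, transform = tf)
    }
  }

  structure(list(width = gp$canvas_width, height = height,
                 layers = layers, tracks = tracks, counts = counts),
            class = "syn_scene")
}

#' Serialize a scene to JSON (the `--dump-scene` debugging output)
#' @param scene a `syn_scene`
#' @param path optional output path; when `NULL` the JSON string is returned
#' @return JSON text (invisibly when written to `path`)
#' @export
scene_to_json <- function(scene, path = NULL) {
  strip_classes <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip_classes)
      attributes(x) <- list(names = names(x))
    } else {
      x <- unclass(x)
      attr(x, "class") <- NULL
    }
    x
  }
  ser <- strip_classes(scene[c("width", "height", "counts", "layers")])
  js <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.syn_scene <- function(x, ...) {
  cat(sprintf("<syn_scene %gx%g: %d ribbons, %d rects, %d features, %d axis prims, %d labels>\n",
              x$width, x$height, length(x$layers$ribbons), length(x$layers$tracks),
              length(x$layers$features), length(x$layers$axes), length(x$layers$labels)))
  invisible(x)
}
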