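---
title: "multisyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{multisyn: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisyn)
```

multisyn renders syntenic relationships among N genomes as an SVG scene. This
vignette is the package's account of how that scene is defined: the
coordinate model, the parameter cascade, the geometry, the numerical
choices, and what the synthetic-data generator does and does not establish.

## Coordinate model

Native coordinates are **1-based, fully closed** intervals, matching the
`seq:start:end` style of region specifiers and the loose whitespace formats
common among Perl-era genomics tools. The PAF converter is the one place a
different convention enters: PAF is 0-based half-open, so a PAF interval
`[s0, e0)` becomes `(s0 + 1, e0)`, which preserves interval length.

Inversions may be encoded in link files by writing *either* side's interval
descending. Internally every record is normalized to ascending coordinates
plus an `orientation` flag (`same`/`inverted`); a record with *both* sides
descending is the same block written backwards, hence `same`. Writers
re-encode inversion by a descending B interval, so parse–write–parse is the
identity on the normalized form.

## The parameter cascade

Drawing parameters resolve through scoped blocks, later layers overriding
earlier ones key by key:

    defaults < SetParaFor=global < GenomeALL < Genome<N>     (genomes)
    defaults < SetParaFor=global < Link<N> < record attrs    (links)

Only the scope *rank* and the file order *within* one scope matter;
interleaving blocks of different scopes is irrelevant, and resolution is a
pure function of the parsed model (both property-tested). Keys are matched
case-insensitively with underscores ignored (`MoveToX` = `move_to_x`).
Unknown keys warn and are retained for forward compatibility. The `global`
scope is a shared namespace: genome keys, link keys and canvas keys
(`canvas_width`, `slot_pitch`, `margin`) may all appear there, and each
resolver picks out the vocabulary it understands.

The configuration *envelope* (the upstream description shows the scope names
and keys but not the file syntax around them) is fixed as: ordered top-level
declarations `Genome = path`, `Feature = <genome index> path`,
`Link = path [iA iB]` (indices default to the adjacent pair `k, k+1`), then
`SetParaFor = <scope>` blocks of `key=value` lines. `#` starts a comment
anywhere.

Selected defaults, with units:

| key | default | meaning |
|---|---|---|
| `canvas_width` | 1200 cu | canvas width (canvas units = SVG px at 96 dpi) |
| `slot_pitch` | 120 cu | vertical spacing of stacked genome slots |
| `chr_height` | 20 cu | chromosome rectangle height |
| `chr_spacing` | 10 cu | gap between chromosome rectangles |
| `zoom_chr` | 1 | per-track uniform scale (> 0) |
| `rotate_chr` | 0° | counter-clockwise, reduced modulo 360 |
| `spe_region_width_ratio` | 1 | feature glyph height ÷ `chr_height` |
| `style` | 2 | link ribbon style (1–5) |
| `style_up_down` | `DownUp` | edge of genome A, edge of genome B |
| `height_ratio` | 1 | scales Bezier control-point offsets (> 0) |
| `opacity` | 0.5 | ribbon fill opacity |

**A deliberate deviation**: the initially sketched default for
`style_up_down` was `UpDown`, but for genomes stacked top-to-bottom that
attaches ribbons to A's *top* and B's *bottom* edge — the two edges facing
*away* from each other — so every default ribbon would cross both
rectangles. The shipped default is `DownUp` (A's bottom edge to B's top
edge, the facing pair), which is what every stacked synteny figure in the
field actually shows. `Up` always means the top edge of that genome's
rectangles in canvas coordinates (y grows downward, the SVG convention),
regardless of where the genome sits.

A `Genome` block cannot set defaults for its incident links; link defaults
come only from `global` and `Link<N>`. This keeps the two cascades
independent and their resolution order-insensitive.

## Track geometry

Each track's transform is `translate(MoveToX, MoveToY) · rotate(RotateChr
about the track origin) · scale(ZoomChr)`, with the origin at the left end
of the first chromosome's baseline. Rotation is applied to the **whole
track**, not per chromosome — the alternative (spinning each rectangle in
place) would break the collinearity of a track's baseline and make link
anchors ambiguous. With `ZoomChr = 1` the transform is an isometry
(property-tested to 1e-9 relative tolerance over random angles).

The bp→x scale is **shared by all tracks** so genome extents are visually
comparable; it is chosen so the widest rendered genome (its windows plus
inter-chromosome gaps) spans the canvas between margins. `ZoomChr` then
scales a whole track about its origin — it is per-genome, not
per-chromosome. Genomes without `MoveToY` stack top-to-bottom in declaration
order at `margin + (i − 1) · slot_pitch`.

A `ZoomRegion = seq:start:end` reduces its track to that single chromosome
slice (intersected with the sequence bounds; an absent sequence is an
error). Links are then clipped: a link wholly outside either window is
dropped; a partial overlap is cut to the window and the partner interval is
rescaled by the same fractions on the *matching* ends — mirrored for
inverted links, since their ends correspond crosswise. The upstream
description is silent on partial overlaps; proportional rescaling is the
choice that keeps the drawn ribbon pointing at the homologous sub-interval.
`kept + dropped = total` always, and no clipped interval exceeds its window
(both property-tested).

## Ribbon geometry

A ribbon is the closed path `a_start → a_end → (cross) → b_end → b_start →
(cross) → a_start`. Style 1 uses straight segments. Styles 2–5 use cubic
Beziers whose control points are offset vertically from the anchors by
`f · HeightRatio · slot_pitch`:

| style | f at A, B | intent |
|---|---|---|
| 2 | 0.5, 0.5 toward the partner | symmetric S-curve (default) |
| 3 | 0.25, 0.25 toward the partner | taut curve |
| 4 | 1.0, 1.0 along each edge's outward normal | deep sag; with `DownDown` gives the wrap-around band |
| 5 | 0.8, 0.2 toward the partner | asymmetric curve |

Offsets are linear in `HeightRatio` with no constant term, so every curved
style converges to the straight quadrilateral as `HeightRatio → 0` (tested:
max perpendicular chord deviation < 1e-6 at ratio 1e-8). The "default
value" that `HeightRatio` is relative to is defined as the slot pitch — the
natural inter-track distance. Control points never leave the anchors'
bounding box expanded by `HeightRatio · slot_pitch` (property-tested), so no
geometry can run away off-canvas.

An inverted link swaps the B-side anchors, which makes the band self-cross —
the standard visual signature of an inversion.

## Axis ticks and features

Tick spacing uses the 1/2/5 rule: the step is the largest `1, 2, 5 × 10^k`
placing 3–8 major ticks inside the window (position 0 is never labelled;
windows too small for 3 ticks fall back to the largest step giving at least
one). Labels carry bp/kb/Mb units chosen from the step. Feature glyphs span
their bp range with height `chr_height × SpeRegionWidthRatio`, vertically
centered, so a ratio of 1.5 overhangs each edge by 25% of the chromosome
height; type defaults (CDS red, UTR blue, TE green, SNP purple) yield to a
record's own `fill`.

## Rendering and determinism

SVG is the canonical output: SVG 1.1, layers in fixed z-order (ribbons under
rectangles under features under axes under labels), only `svg/g/rect/path/
line/text` elements, a generic font stack, and every coordinate printed at
exactly 3 decimals. Identical scenes therefore produce byte-identical files
on any platform — which is what makes golden-file testing of figures
possible. Chromosome rectangles default to rounded caps (`rx = chr_height /
2`), switchable with `rounded_ends = 0`. Per-track transforms are emitted as
SVG `matrix()` attributes rather than baking rotated rectangles into path
outlines.

PNG output is optional-dependency gated: the first available backend among
the `rsvg` package, `rsvg-convert`, or `cairosvg` is used; with none
installed the request fails with a clear message after the SVG has been
written.

## The fixture generator

`make_fixture()` states a small but structured comparative-genomics world:
by default 3 genomes × 2 chromosomes of 0.5–2 Mb, 8 syntenic blocks per
adjacent pair covering 2–25% of a chromosome, one fifth of them inverted,
and 6 highlighted features — a deliberately desk-scale analogue of a
several-hundred-Mb multi-accession comparison (the tool is intended for up
to 20 genomes, which the generator also caps). One derived PRNG stream per
file type means adding a file type never perturbs the others, and a seed
fully determines every output byte.

For every adjacent pair the generator also writes PAF, `show-coords -T`,
SyRI and MCScanX dialect files *encoding exactly the same links* (MCScanX
blocks get two single-bp genes at the interval endpoints, so the block span
min–max reproduces the interval exactly). Converting them must reproduce the
native link set — the converters' principal oracle, run over 50 seeds in the
acceptance suite.

What a green fixture-based test does **not** establish: behaviour on real
aligner output with overlapping, nested or many-to-many blocks; fragmented
assemblies with thousands of contigs; label collision at high genome counts;
or the aesthetics of any particular published figure. The fixtures exercise
formats, geometry and determinism, not biological realism.

## Known limitations

- MUMmer support targets `show-coords -T` tabular output only, not `.delta`.
- No automatic avoidance of overlapping tracks under user-supplied
  transforms; layout freedom means users can draw genomes on top of each
  other.
- Circular (Circos-style) tracks and gene-structure-aware feature drawing
  beyond flat glyph rectangles are out of scope.
- SyRI conversion keeps interval-bearing top-level record classes only;
  alignment-level children (`*AL`) and point records (SNP/INS/DEL) are
  intentionally dropped.
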