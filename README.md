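# multisyn

Flexible, configuration-driven visualization of synteny across multiple
genomes, for comparative genomicists who have whole-genome alignments (or
gene-anchor collinearity) between a set of assemblies and want a
publication-ready figure without writing plotting code.

## What it draws

Each genome is a **track**: its chromosomes as rounded rectangles on a
horizontal baseline, in file order, with optional coordinate ticks, labels
and highlighted feature regions (CDS, UTR, TE, SNP, ...). Syntenic blocks
between two genomes are **ribbons** — filled bands joining an interval on one
track to its counterpart on another. An inverted block self-crosses. Every
track carries its own affine transform

    T = translate(MoveToX, MoveToY) · rotate(RotateChr) · scale(ZoomChr)

so genomes can be moved, rotated and scaled independently (stacked,
triangular or free-form layouts), and a `ZoomRegion=seq:start:end` restricts
a track to a region of interest. Ribbons come in five styles: a straight
quadrilateral (style 1) and four cubic-Bezier profiles (styles 2–5) whose
control points sit `f(style) · HeightRatio · slot_pitch` canvas units from
the anchors, so `HeightRatio → 0` degenerates every style to the straight
band. `StyleUpDown` picks which horizontal edge (Up = top, Down = bottom) of
each genome's rectangles the ribbon attaches to.

All coordinates are 1-based, fully closed intervals. Input files are plain
whitespace-delimited text (gzip accepted): genome files (`seq start end
[key=value ...]`), link files (`seqA startA endA seqB startB endB
[key=value ...]`, inversion encoded by one descending interval), feature
files (like genome files, IDs may repeat). Converters turn minimap2 PAF
(0-based half-open, converted), MUMmer `show-coords -T`, MCScanX
`.collinearity` (+ a gene position table) and SyRI output into the link
format. Drawing parameters cascade through scoped configuration blocks:

    defaults < SetParaFor=global < GenomeALL < Genome<N>   (genomes)
    defaults < SetParaFor=global < Link<N> < per-record attributes

## Worked example

```r
library(multisyn)
fx <- make_fixture("demo", seed = 42, n_genomes = 3, n_links = 6)
report <- cmd_plot(fx$config, "demo/figure")
```

prints

```
run report
  genomes         3
  chromosomes     6
  links_total     12
  links_kept      12
  links_clipped   0
  links_dropped   0
  features        6
  wrote demo/figure.svg
```

Three genomes of two chromosomes each were laid out in stacked slots; the
two adjacent genome pairs contributed 6 links each, all of which survived
window clipping (`links_kept + links_dropped = links_total` always holds);
six highlighted features were drawn on genome 1. `demo/figure.svg` is a
self-contained SVG 1.1 document; identical inputs reproduce it byte for
byte. The same figure from a shell:

```sh
Rscript inst/cli/multisyn plot -c demo/plot.conf -o demo/figure --dump-scene
Rscript inst/cli/multisyn convert paf -i aln.paf -o out --min-len 1000
Rscript inst/cli/multisyn fixtures -o demo2 --genomes 4 --seed 7
```

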