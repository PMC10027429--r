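Package: multisyn
Title: Flexible Multi-Genome Synteny Visualization
Version: 0.1.0
Authors@R:
    person("multisyn", "developers", email = "multisyn@example.org",
           role = c("aut", "cre"))
Description: Configuration-driven rendering of syntenic relationships and
    genomic features across multiple genomes as customizable SVG and PNG
    figures. Reads simple whitespace-delimited genome, link and feature
    files; converts minimap2 PAF, MUMmer show-coords, MCScanX collinearity
    and SyRI outputs into its link format; resolves a scoped parameter
    cascade; lays out genome tracks under per-genome affine transforms with
    region zooming; and draws links as straight or Bezier ribbons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    rsvg,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
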