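Package: pafkit
Title: CIGAR-Aware Manipulation of Pairwise Alignments in PAF Format
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for post-processing pairwise genome alignments in the
    Pairwise mApping Format (PAF) while keeping CIGAR strings exact.
    Provides coordinate liftover that emits trimmed alignment records,
    resolution of overlapping query alignments by cumulative-score
    maximization, splitting of alignments at large insertions and
    deletions, contig reorientation and pseudo-scaffolding,
    per-alignment identity statistics in a BED dialect, a deterministic
    synthetic-alignment simulator with a base-level truth map, and a
    static miropeats-style ribbon-plot renderer (SVG). Subcommands
    compose through standard streams via a thin command-line dispatcher.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
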