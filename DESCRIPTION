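Package: editpause
Title: Junction Profiling and Pause-Site Detection for U-Indel RNA
    Editing Amplicons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of amplicon deep-sequencing reads from
    kinetoplastid mitochondrial mRNAs undergoing uridine
    insertion/deletion (U-indel) editing.  Builds an editing-site
    coordinate system from a pre-edited/fully-edited reference pair,
    reduces each read to its per-editing-site U-count vector by exact
    non-T backbone matching, classifies reads as pre-edited, partially
    edited or fully edited, calls per-read junction boundaries (junction
    start and end sites), aggregates normalized per-site junction-end
    profiles, and detects exacerbated junction end sites (editing pause
    sites) between two conditions.  Includes a synthetic read generator
    that emulates progressive 3'-to-5' editing with planted pause sites
    and substitution sequencing errors, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
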