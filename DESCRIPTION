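Package: crucarb
Title: Annotation, Expression and Distance Analysis of Coral Alpha-Carbonic Anhydrases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing alpha-carbonic anhydrase (alpha-CA)
    repertoires from coral transcript sequences: open-reading-frame calling and
    translation, physicochemical profiling (molecular weight, Bjellqvist
    isoelectric point, Kyte-Doolittle hydropathy, sequon scans), heuristic
    subcellular-localization classification (signal peptide, transmembrane,
    GPI anchor), active-site annotation in human carbonic anhydrase II (CAII)
    residue numbering via pairwise global alignment (zinc-binding triad, proton
    shuttle, gatekeepers, QSPID motif, disulfide-bridge cysteines), carbonic
    anhydrase related protein (CARP) calling with codon-level
    transition/transversion analysis of the His-His-His to Arg-His-Gln
    conversion, efficiency-corrected relative qPCR expression (Pfaffl),
    Poisson-corrected protein distances with neighbor-joining trees, and
    seed-deterministic synthetic-data generators with ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
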