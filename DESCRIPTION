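Package: ubiscreen
Title: Analysis Toolkit for Ubiquitin E2 Knockdown Proteome Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the computational pipeline for multiplexed (TMT)
    proteome screens of ubiquitin-conjugating enzyme (E2) knockdowns:
    per-condition differential protein abundance against in-set controls,
    integration with RNA-seq to call transcription-independent protein
    modulation, spectral-count scoring and filtering of IP-MS interactomes,
    batch-aware pairwise similarity statistics (R-squared, similarity score,
    intra-/extra-batch z-scores), peroxisomal-panel summaries, and
    quantification of peroxisomal protein import from multichannel
    fluorescence images (puncta segmentation and PTS1/PMP70 overlap
    classification). Ships synthetic-data generators with known ground truth
    for every input the pipeline consumes, so each analysis stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    tiff,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
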