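Package: herbocr
Title: Ensemble OCR with Visual-Similarity Consensus for Herbarium Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semi-automated digitization of typewritten natural
    history specimen labels. Reconciles crowdsourced label bounding-box
    annotations (IoU, outline averaging, majority-rule typing), applies a
    chain of document image pre-processing variants (blur/scale, orientation,
    projection-profile deskew, Sauvola binarization, despeckle/hole filling),
    runs pluggable OCR engine adapters, and merges the resulting text streams
    into a consensus transcription via progressive multiple sequence alignment
    under a visual-similarity substitution matrix with affine gap penalties.
    Includes Levenshtein outlier pruning, lexicon-based post-correction, a
    full sweep over pipeline permutations scored against a verbatim gold
    standard, and a synthetic label renderer plus noisy-OCR simulator so every
    stage is testable without installed OCR engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'RcppExports.R'
    'boxes-classes.R'
    'boxes.R'
    'preproc-classes.R'
    'engines-classes.R'
    'similarity.R'
    'consensus-classes.R'
    'consensus.R'
    'engines.R'
    'font.R'
    'render.R'
    'textclean.R'
    'synthetic.R'
    'pipeline-classes.R'
    'pipeline.R'
    'evaluate.R'
    'herbocr-package.R'
    'preproc.R'
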