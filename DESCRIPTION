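Package: gridner
Title: Word-Pair Relation Grid Tagging for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Biomedical named entity recognition by word-pair relation
    classification instead of sequence labeling. Sentences are encoded as an
    N x N relation grid over word pairs using Next-Neighboring-Word (NNW) and
    typed Tail-Head-Word (THW) relations, classified by a neural stack built
    from a prefix-augmented transformer encoder, a bidirectional LSTM, a
    conditional-layer-normalization pair grid with distance and region
    embeddings, and a single dilated convolution. Attention-head diversity is
    encouraged by an instance-discrimination auxiliary loss over pooled
    per-head received-attention vectors, fused from prefix-inclusive and
    prefix-exclusive poolings. Includes CoNLL BIO corpus I/O, a synthetic
    biomedical corpus generator, grid encoding/decoding, entity-level
    precision/recall/F1 evaluation, training with AdamW, attention heatmap
    export, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
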