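Package: ringmem
Title: Decoding and Replay Analysis of Multi-Sequence Working Memory on Ring Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for working-memory experiments in which
    participants memorize short sequences of items whose locations and colors
    live on circular feature spaces. Provides a synthetic-data generator with
    known ground truth (ring-valued trial designs with aligned vs. misaligned
    trajectory conditions, von Mises behavioral reports, forward-model
    multi-sensor epochs with optional planted sequential replay), circular
    behavioral statistics (response error, memory precision, trajectory error,
    circular correlation, group binned correlation), time-resolved inverted
    encoding model (IEM) decoding with leave-one-block-out cross-validation
    and a slope score, sequential-replay detection via lagged cross-correlation
    asymmetry and transition-matrix similarity with a label-shuffle permutation
    null, cluster-based permutation testing, and eight-way trajectory-distance
    classification with Morlet alpha-band power features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
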