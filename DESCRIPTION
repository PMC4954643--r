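Package: mirduplex
Title: Discriminative miRNA Target Prediction from AGO CLIP and CLASH
    Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains and applies a two-part discriminative model of miRNA
    targeting from crosslinking-derived interaction data. A structural
    support vector machine learns position-dependent scoring parameters
    for local miRNA-mRNA duplex alignment (base-pair, loop-opening and
    loop-extension features, with adenosine-only pairing opposite miRNA
    position 1) from CLASH chimeric reads and AGO CLIP sites, alternating
    between duplex re-alignment and margin-based weight updates. A second
    kernel SVM models AGO binding preferences from weighted-degree string
    kernels on the 30-nt flanks of canonical seed matches and a radial
    basis kernel on positions within 3'UTR isoforms, trained across cell
    types with a multi-task kernel. Includes positional oligomer
    importance matrices (POIMs) and per-position score decomposition for
    model interpretation, rank-sum motif enrichment against probe
    intensity tables with a label-permutation false discovery rate,
    held-out-family evaluation (auROC, auPR, auPR50), and a synthetic
    data generator with planted duplex weights, flank motifs and
    positional bias for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    kernlab,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
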