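Package: airrnet
Title: Multidimensional Similarity Networks for Adaptive Immune Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pairwise similarity between adaptive immune receptor
    repertoires (AIRR) across six immunological features (clonal evenness
    profiles, positional amino-acid frequencies, Levenshtein-distance-1
    sequence-similarity network architecture, clonal overlap, germline
    V(D)J gene usage, and gapped k-mer occurrence), condenses the
    per-feature similarity matrices into a composite similarity network,
    and provides network-level analyses (edge thresholding, local
    similarity, reference-repertoire identification), cross-feature
    redundancy via normalized mutual information, and a seeded synthetic
    repertoire generator with motif-implantation, hub-deletion and
    synonymous-codon perturbations for ground-truth sensitivity analysis.
    Optionally integrates a gene-expression similarity feature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
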