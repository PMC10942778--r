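Package: posembed
Title: Small Positional Embeddings of Protein Sequences for Profile and
    Structure Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts protein sequences into small positional embeddings --
    positional amino-acid probability profiles and 3Di structure-alphabet
    sequences -- that plug directly into profile-HMM and structure search
    engines.  Implements multi-pass masked-marginal profile prediction
    against a pluggable embedder, writers and readers for HMMER3 '.hmm'
    and HH-suite '.hhm' profile formats, profile-sampled multiple sequence
    alignments, paired sequence databases in an MMseqs2-style data/index
    layout, a two-layer 1D convolutional head mapping positional embeddings
    to 3Di states with a weighted cross-entropy loss and AdamW training,
    maximum-likelihood mixture-Dirichlet prior estimation from structure-
    alphabet alignment columns, and remote-homology benchmark statistics
    (identity-binned top-hit accuracy and per-query sensitivity to the
    first false positive).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
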