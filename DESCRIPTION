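Package: pepspace
Title: Molecular Similarity Networks for Chemical Space Analysis of Bioactive Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns raw peptide amino-acid sequences into an optimized
    molecular-descriptor space and mines the resulting similarity networks.
    Descriptors are computed by applying statistical and aggregation operators
    (including ordered weighted averaging and sliding-window neighborhood
    smoothing) to amino-acid property vectors and group memberships. A
    two-stage unsupervised feature selection combines entropy ranking with
    correlation-based redundancy filtering and a greedy backward elimination
    that maximizes an entropy-minus-mutual-information merit function, with
    Procrustes goodness-of-fit to compare the original and reduced descriptor
    spaces. The selected descriptor space is translated into weighted
    similarity graphs: thresholded chemical space networks (CSN), sparse
    half-space proximal networks (HSPN), and k-nearest-neighbor embeddings of
    new sequences. Graph mining covers Louvain communities, weighted
    modularity, harmonic and community hub-bridge centralities, top-k
    subnetwork extraction, and redundancy filtering of central peptides by
    Smith-Waterman sequence identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
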