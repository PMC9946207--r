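Package: subclust
Title: Unsupervised Detection of Biosynthetic Sub-Clusters in Bacterial Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sub-clusters (groups of co-evolving genes encoding the
    biosynthesis of one chemical moiety) inside bacterial biosynthetic gene
    clusters (BGCs). Genes are tokenised as combinations of (sub)Pfam domains,
    redundant BGCs are removed via an Adjacency-Index similarity network, and
    sub-clusters are detected both by exact hypergeometric tests on gene
    adjacency and co-localisation followed by Benjamini-Yekutieli correction
    and iterative maximal-clique extraction, and by a latent Dirichlet
    allocation topic model whose topics act as sub-cluster motifs. Detected
    sub-cluster features can be correlated with mass-spectral substructure
    motifs across strains using an asymmetric co-occurrence score with
    permutation-based significance. Includes generators for synthetic
    tokenised corpora and paired strain presence matrices with planted ground
    truth, and a small SVG visualiser for per-BGC matches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
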