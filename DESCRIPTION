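Package: pin2target
Title: Drug-Target Prioritization from Protein-Interaction-Network Embeddings
Version: 0.1.0
Authors@R:
    person("pin2target", "developers", email = "pin2target@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline that prioritizes candidate drug-target
    genes from a directed protein-protein interaction network (PIN). Adjacency
    rows of the PIN are embedded with a symmetric deep autoencoder; nine
    network-topology metrics (degrees, betweenness, closeness, PageRank,
    clustering coefficient, nearest-neighbor degree, bow-tie layer membership,
    and controllability-based indispensability) characterize the latent space;
    an ensemble of gradient-boosted tree classifiers trained on SMOTE-balanced
    resampled datasets ranks genes by mean positive-class probability;
    putative targets drive overlap-based drug-repositioning inference and
    hypergeometric pathway over-representation analysis. A seeded synthetic
    data generator provides scale-free PINs with a planted positive class so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
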