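Package: DualGraphClust
Title: Enumeration, Persistent Spectral Featurization and Clustering of
    RNA Dual-Graph Topologies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for exploring the universe of RNA-like motifs through
    coarse-grained dual graphs, in which double-helical stems are vertices
    and connecting single strands are edges. The package enumerates all
    non-isomorphic dual-graph topologies for a given vertex range,
    characterizes each topology with nineteen persistent-spectral-graph
    descriptors derived from a distance filtration of simplicial
    complexes, partitions the resulting feature space into RNA-like and
    non-RNA-like groups with six unsupervised clustering algorithms
    anchored on known-RNA labels, ranks hypothetical topologies by
    proximity to the RNA-like cluster center, computes persistence
    barcodes and Betti-number summaries, and decides whether a topology is
    separable into smaller valid dual graphs or irreducible.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    mclust,
    kernlab,
    cluster,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
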