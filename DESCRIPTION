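Package: pmtvec
Title: Alignment-Free Protein Sequence Comparison via Pseudo-Markov
    Transition Vectors
Version: 0.1.0
Authors@R:
    person("pmtvec", "developers", email = "pmtvec@example.org",
           role = c("aut", "cre"))
Description: Encodes protein sequences into 440-dimensional feature
    vectors composed of a 400-dimensional pseudo-Markov transition
    probability block among the 20 standard amino acids, a
    20-dimensional content-ratio block, and a 20-dimensional
    position-ratio block.  Pairwise Euclidean (or Hamming) distances
    between feature vectors give an alignment-free distance matrix,
    which can be benchmarked against an alignment-based reference
    matrix (e.g. ClustalW) by Pearson correlation of the
    upper-triangular entries.  Includes FASTA input, CSV/PHYLIP
    distance-matrix interchange, a first-order Markov sequence
    simulator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
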