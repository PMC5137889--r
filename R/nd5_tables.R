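#' Published ND5 benchmark distance matrices
#'
#' Two 9 x 9 distance matrices over the ND5 (NADH dehydrogenase subunit
#' 5) proteins of nine mammals — a standard benchmark set for protein
#' sequence comparison (human, gorilla, pigmy and common chimpanzee,
#' fin and blue whale, rat, mouse, opossum; NCBI accessions AP_000649,
#' NP_008222, NP_008209, NP_008196, NP_006899, NP_007066, NP_004902,
#' NP_904338, NP_007105).
#'
#' `method` holds the published pairwise Euclidean distances among the
#' nine 440-D pseudo-Markov feature vectors; `clustalw` holds the
#' alignment-based ClustalW distances for the same nine proteins, the
#' standard reference matrix for correlation benchmarking of
#' alignment-free methods.  Both are bundled in the upper-triangular
#' form in which such tables are printed and mirrored to full symmetry
#' on load; the Pearson correlation of their upper triangles is the
#' headline benchmark figure (0.962).
#'
#' @return Named list with elements `method` and `clustalw`, each a
#'   labeled symmetric 9 x 9 matrix.
#' @export
#' @examples
#' tabs <- nd5_reference_matrices()
#' matrix_correlation(tabs$method, tabs$clustalw)
nd5_reference_matrices <- function() {
  path <- function(f) system.file("extdata", f, package = "pmtvec",
                                  mustWork = TRUE)
  list(
    method = read_distance_matrix(path("nd5_method_distances.csv"), "csv"),
    clustalw = read_distance_matrix(path("nd5_clustalw_distances.csv"), "csv")
  )
}
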