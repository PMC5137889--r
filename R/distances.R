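#' Distance between two feature vectors
#'
#' `euclidean` is the root-sum-of-squares over all shared coordinates,
#' `d(S, T) = sqrt(sum_i (V_S[i] - V_T[i])^2)`.  `hamming` counts the
#' coordinates whose values differ by more than `hamming_tolerance`
#' (default 0, i.e. exact inequality) — the natural reading of a Hamming
#' distance on real-valued vectors, exposed as a configurable
#' interpretation.
#'
#' @param a,b Numeric vectors of equal length (same block selection and
#'   alphabet order).
#' @param metric `"euclidean"` or `"hamming"`.
#' @param hamming_tolerance Non-negative real; ignored by `euclidean`.
#' @return A single non-negative number.
#' @export
#' @examples
#' vector_distance(encode_protein("LLAL"), encode_protein("AALL"))
vector_distance <- function(a, b, metric = c("euclidean", "hamming"),
                            hamming_tolerance = 0) {
  metric <- match.arg(metric)
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b),
         call. = FALSE)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (metric == "euclidean") sqrt(sum((a - b)^2))
  else as.numeric(sum(abs(a - b) > hamming_tolerance))
}

#' Pairwise distance matrix for a set of sequences
#'
#' Encodes every sequence with the selected blocks and returns the
#' symmetric, zero-diagonal matrix of pairwise distances in input label
#' order.  Block subsets reproduce the ablated encodings (position-only,
#' content-only, content+position).
#'
#' @param seqs Named character vector of residue strings (>= 2, distinct
#'   labels).
#' @param alphabet An [aa_alphabet()].
#' @param metric,hamming_tolerance See [vector_distance()].
#' @param blocks See [encode_protein()].
#' @return Labeled symmetric numeric matrix.
#' @export
pairwise_matrix <- function(seqs, alphabet = aa_alphabet(),
                            metric = c("euclidean", "hamming"),
                            blocks = "PCD", hamming_tolerance = 0) {
  metric <- match.arg(metric)
  if (length(seqs) < 2L)
    stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]),
               collapse = ", "), call. = FALSE)
  X <- encode_set(seqs, alphabet, blocks)
  m <- if (metric == "euclidean") {
    as.matrix(stats::dist(X, method = "euclidean"))
  } else {
    n <- nrow(X)
    h <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      h[i, j] <- h[j, i] <- sum(abs(X[i, ] - X[j, ]) > hamming_tolerance)
    }
    h
  }
  distance_matrix(m, rownames(X))
}

#' Pearson correlation between two distance matrices
#'
#' Aligns the two matrices by label (by name, not position), then
#' correlates the strictly-upper-triangular entries — `k(k-1)/2` values
#' for `k` sequences.  Diagonal zeros are excluded: they would inflate
#' agreement, and the symmetric lower half adds no information.
#'
#' Because only the strict upper triangle enters the correlation, the
#' inputs need not be metric distance matrices: any labeled symmetric
#' matrices (e.g. affine-transformed ones) are accepted.
#'
#' @param m1,m2 Labeled symmetric matrices over the same label set.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
matrix_correlation <- function(m1, m2) {
  check_sym <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || is.null(rownames(m)))
      stop("need a labeled square matrix", call. = FALSE)
    if (any(abs(m - t(m)) > 1e-9))
      stop("matrix asymmetric beyond tolerance 1e-9", call. = FALSE)
    m
  }
  m1 <- check_sym(m1)
  m2 <- check_sym(m2)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("label mismatch between the two matrices", call. = FALSE)
  m2 <- m2[rownames(m1), rownames(m1)]
  ut <- upper.tri(m1)
  if (sum(ut) < 3L)
    stop("need at least 3 pairs for a correlation", call. = FALSE)
  stats::cor(m1[ut], m2[ut], method = "pearson")
}
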