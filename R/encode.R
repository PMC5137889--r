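#' Tally residue occurrences, adjacent pairs, and position sums
#'
#' For a sequence `S = S_1 ... S_N` over the ordered alphabet
#' `A_1, ..., A_20`, counts:
#' * `n[i]` — occurrences of residue `A_i` (`sum(n) == N`),
#' * `pairs[i, j]` — occurrences of the ordered adjacent pair `A_i A_j`
#'   among the `N - 1` overlapping positions (`sum(pairs) == N - 1`),
#' * `s[i]` — sum of the 1-based positions at which `A_i` occurs
#'   (`sum(s) == N * (N + 1) / 2`),
#' plus the alphabet indices `u` of the first and `v` of the last
#' residue.  All counts are exact integers; division to probabilities
#' happens only in [transition_probabilities()] so the pair-count
#' marginal identities can be checked exactly.
#'
#' The row marginal of `pairs` is `n[i]`, minus one for the final
#' residue's row; the column marginal is `n[j]`, minus one for the first
#' residue's column.
#'
#' @param seq A single residue string (length >= 2).
#' @param alphabet An [aa_alphabet()].
#' @return An object of class `aa_counts`: list with `n`, `pairs`, `s`,
#'   `u`, `v`, `N`.
#' @export
#' @examples
#' ct <- tally("LLAL")
#' ct$n[["L"]]      # 3
#' ct$pairs["L", "A"]
tally <- function(seq, alphabet = aa_alphabet()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 2L)
    stop("sequence length must be >= 2", call. = FALSE)
  idx <- residue_indices(seq, alphabet)
  N <- length(idx)
  lv <- factor(idx, levels = 1:20)
  n <- as.integer(table(lv))
  pairs <- table(factor(idx[-N], levels = 1:20),
                 factor(idx[-1], levels = 1:20))
  pairs <- matrix(as.integer(pairs), 20L, 20L)
  s <- vapply(split(seq_len(N), lv), sum, 0)
  names(n) <- names(s) <- alphabet$order
  dimnames(pairs) <- list(alphabet$order, alphabet$order)
  structure(
    list(n = n, pairs = pairs, s = s,
         u = idx[1], v = idx[N], N = N,
         alphabet = alphabet$order),
    class = "aa_counts"
  )
}

#' Pseudo-Markov transition probability matrix
#'
#' Empirical conditional frequency of `A_j` immediately following `A_i`:
#' `P[i, j] = pairs[i, j] / n[i]`, except that for the row of the final
#' residue (`A_i = S_N`) the denominator is `n[i] - 1` — the endpoint
#' correction that makes every defined row sum to exactly 1.  A row
#' whose denominator is 0 (residue absent, or occurring exactly once as
#' the final residue) is defined to be all zeros.
#'
#' @param counts An `aa_counts` object from [tally()].
#' @return 20 x 20 row-stochastic (or zero-row) numeric matrix.
#' @export
transition_probabilities <- function(counts) {
  stopifnot(inherits(counts, "aa_counts"))
  denom <- as.numeric(counts$n)
  denom[counts$v] <- denom[counts$v] - 1
  P <- counts$pairs / ifelse(denom > 0, denom, Inf)
  P[denom == 0, ] <- 0
  P
}

#' Content ratio vector
#'
#' `C[i] = n[i] / N`, the fraction of positions occupied by residue
#' `A_i`; sums to 1.
#'
#' @inheritParams transition_probabilities
#' @return Named 20-vector.
#' @export
content_ratios <- function(counts) {
  stopifnot(inherits(counts, "aa_counts"))
  counts$n / counts$N
}

#' Position ratio vector
#'
#' `D[i] = 2 * s[i] / (N * (N + 1))`, where `s[i]` is the sum of the
#' 1-based positions of residue `A_i`; a centre-of-mass-like summary of
#' where each residue sits.  Sums to 1.
#'
#' @inheritParams transition_probabilities
#' @return Named 20-vector.
#' @export
position_ratios <- function(counts) {
  stopifnot(inherits(counts, "aa_counts"))
  2 * counts$s / (counts$N * (counts$N + 1))
}

#' Encode a protein sequence into its feature vector
#'
#' Concatenates, in fixed P, C, D order, the selected blocks of the
#' 440-dimensional feature vector: the 400-D pseudo-Markov transition
#' block `P` flattened row-major (`P_1,1, ..., P_1,20, P_2,1, ...`),
#' the 20-D content-ratio block `C`, and the 20-D position-ratio block
#' `D`.  Block subsets (e.g. `"C"`, `"CD"`) support ablation analyses;
#' the relative order is always preserved.
#'
#' @param seq A single residue string.
#' @param alphabet An [aa_alphabet()].
#' @param blocks String naming the blocks to keep, a non-empty subset of
#'   `"PCD"`.
#' @return Named numeric feature vector of class `aa_feature` with
#'   attributes `blocks`, `N`, `u`, `v`, `alphabet`.
#' @export
#' @examples
#' v <- encode_protein("LLAL")
#' v[v != 0]
encode_protein <- function(seq, alphabet = aa_alphabet(), blocks = "PCD") {
  sel <- parse_blocks(blocks)
  ct <- tally(seq, alphabet)
  res <- alphabet$order
  out <- numeric(0)
  if ("P" %in% sel) {
    P <- transition_probabilities(ct)
    p <- as.vector(t(P))   # row-major: i outer, j inner
    names(p) <- paste0("P_", rep(res, each = 20L), "_", rep(res, 20L))
    out <- c(out, p)
  }
  if ("C" %in% sel) {
    C <- content_ratios(ct)
    names(C) <- paste0("C_", res)
    out <- c(out, C)
  }
  if ("D" %in% sel) {
    D <- position_ratios(ct)
    names(D) <- paste0("D_", res)
    out <- c(out, D)
  }
  structure(out, class = "aa_feature", blocks = paste(sel, collapse = ""),
            N = ct$N, u = ct$u, v = ct$v, alphabet = res)
}

parse_blocks <- function(blocks) {
  stopifnot(is.character(blocks), length(blocks) == 1L)
  sel <- unique(strsplit(toupper(blocks), "")[[1]])
  if (length(sel) == 0L || !all(sel %in% c("P", "C", "D")))
    stop("`blocks` must be a non-empty subset of \"PCD\"", call. = FALSE)
  # canonical P, C, D order regardless of how the subset was written
  intersect(c("P", "C", "D"), sel)
}

#' Encode a set of sequences into a feature matrix
#'
#' @param seqs Named character vector of residue strings.
#' @param alphabet An [aa_alphabet()].
#' @param blocks See [encode_protein()].
#' @return Numeric matrix, one row per sequence, labeled columns.
#' @export
encode_set <- function(seqs, alphabet = aa_alphabet(), blocks = "PCD") {
  seqs <- validate_proteins(seqs, alphabet)
  rows <- lapply(seqs, encode_protein, alphabet = alphabet, blocks = blocks)
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(names(seqs), names(rows[[1]]))
  m
}

#' Mixed content-transition contraction of a feature vector
#'
#' `delta(v, j) = sum_i C_i * P_{i, j}`: the content-weighted
#' probability of arriving at residue `A_j`.  Requires a vector encoded
#' with at least the P and C blocks.
#'
#' @param v An `aa_feature` from [encode_protein()].
#' @param j Alphabet index 1..20, or a one-letter residue code.
#' @return A single number.
#' @export
delta <- function(v, j) {
  stopifnot(inherits(v, "aa_feature"))
  res <- attr(v, "alphabet")
  sel <- strsplit(attr(v, "blocks"), "")[[1]]
  if (!all(c("P", "C") %in% sel))
    stop("delta() needs a vector encoded with the P and C blocks",
         call. = FALSE)
  j <- resolve_index(j, res)
  Pcol <- v[paste0("P_", res, "_", res[j])]
  Cvec <- v[paste0("C_", res)]
  sum(Cvec * Pcol)
}

resolve_index <- function(j, res) {
  if (is.character(j)) j <- match(toupper(j), res)
  if (is.na(j) || j < 1L || j > 20L)
    stop("`j` must be an alphabet index 1..20 or a residue code",
         call. = FALSE)
  as.integer(j)
}

#' Verify the delta identity on one sequence
#'
#' The contraction `sum_i C_i P_{i,j}` has an exact closed form in terms
#' of `C_j`, the sequence length `N`, and the transition row of the last
#' residue `A_v`: it equals `C_j + P_{v,j} / N`, minus `1 / N` when
#' `A_j` is the first residue.  (When the last residue occurs only once
#' its P row is identically zero, which gives the degenerate form
#' automatically.)  The identity holds exactly for every sequence, so
#' any residual beyond floating-point noise indicates an encoder bug.
#'
#' @param seq A single residue string.
#' @param alphabet An [aa_alphabet()].
#' @param tol Maximum residual regarded as a pass.
#' @return Data frame with one row per alphabet residue: `residue`,
#'   `delta`, `closed_form`, `residual`; attributes `max_residual` and
#'   `pass`.
#' @export
#' @examples
#' rep <- verify_delta_identity("LLAL")
#' attr(rep, "max_residual")
verify_delta_identity <- function(seq, alphabet = aa_alphabet(),
                                  tol = 1e-12) {
  v <- encode_protein(seq, alphabet, blocks = "PC")
  res <- attr(v, "alphabet")
  N <- attr(v, "N")
  u <- attr(v, "u")
  last <- attr(v, "v")
  lhs <- vapply(1:20, function(j) delta(v, j), 0)
  Prow_v <- as.numeric(v[paste0("P_", res[last], "_", res)])
  Cvec <- as.numeric(v[paste0("C_", res)])
  rhs <- Cvec + Prow_v / N - (seq_len(20) == u) / N
  out <- data.frame(residue = res, delta = lhs, closed_form = rhs,
                    residual = abs(lhs - rhs))
  structure(out, max_residual = max(out$residual),
            pass = max(out$residual) <= tol)
}
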