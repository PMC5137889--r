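#' Specify a random-sequence model
#'
#' A generative model for synthetic protein sequences: i.i.d. sampling
#' from `composition`, or — when `transition` is supplied — a
#' first-order Markov chain with initial state drawn from `composition`
#' and row-stochastic transition matrix `transition`.  Used to emulate
#' the inputs the encoder consumes (and, with two separated models, a
#' two-family dataset) without any download.
#'
#' @param length Sequence length, >= 2.
#' @param composition 20 non-negative target residue frequencies summing
#'   to 1 (within 1e-9).  Default uniform.
#' @param transition Optional 20 x 20 row-stochastic matrix (rows sum to
#'   1 within 1e-9).
#' @param seed Integer seed; a model is deterministic given its seed.
#' @return An object of class `seq_model`.
#' @export
sequence_model <- function(length, composition = rep(1 / 20, 20),
                           transition = NULL, seed = 1L) {
  if (length < 2L) stop("`length` must be >= 2", call. = FALSE)
  if (length(composition) != 20L || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("`composition` must be 20 non-negative frequencies summing to 1",
         call. = FALSE)
  if (!is.null(transition)) {
    transition <- as.matrix(transition)
    if (!all(dim(transition) == c(20L, 20L)) || any(transition < 0) ||
        any(abs(rowSums(transition) - 1) > 1e-9))
      stop("`transition` must be a 20 x 20 row-stochastic matrix",
           call. = FALSE)
  }
  structure(
    list(length = as.integer(length), composition = composition,
         transition = transition, seed = as.integer(seed)),
    class = "seq_model"
  )
}

# Run `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate synthetic protein sequences
#'
#' Deterministic for a fixed model seed; sequence `k` of `n` is drawn
#' from an independent substream (seed + k - 1) so that any prefix of
#' the set is stable as `n` grows.  Labels encode the model seed.
#'
#' @param model A [sequence_model()].
#' @param n Number of sequences.
#' @param alphabet An [aa_alphabet()] supplying the residue order.
#' @return Named character vector of residue strings.
#' @export
#' @examples
#' simulate_proteins(sequence_model(30, seed = 7), n = 2)
simulate_proteins <- function(model, n = 1L, alphabet = aa_alphabet()) {
  stopifnot(inherits(model, "seq_model"))
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  seqs <- vapply(seq_len(n), function(k)
    with_seed(model$seed + k - 1L, draw_sequence(model, alphabet)), "")
  names(seqs) <- sprintf("sim%d_%d", model$seed, seq_len(n))
  seqs
}

draw_sequence <- function(model, alphabet) {
  N <- model$length
  if (is.null(model$transition)) {
    idx <- sample.int(20L, N, replace = TRUE, prob = model$composition)
  } else {
    # inverse-CDF chain walk over precomputed cumulative rows
    cum <- t(apply(model$transition, 1L, cumsum))
    u <- stats::runif(N)
    idx <- integer(N)
    idx[1] <- sample.int(20L, 1L, prob = model$composition)
    for (t in 2:N)
      idx[t] <- findInterval(u[t], cum[idx[t - 1L], ]) + 1L
  }
  paste(alphabet$order[idx], collapse = "")
}

#' Generate labeled sequence families
#'
#' One family per model; labels are `fam<f>_<k>`.  With sufficiently
#' separated models (different compositions or transition structure) all
#' within-family distances fall below all between-family distances in
#' the resulting distance matrix.
#'
#' @param n_per_family Sequences per family (0 gives an empty set).
#' @param models List of >= 2 [sequence_model()]s.
#' @param alphabet An [aa_alphabet()].
#' @return Named character vector; names carry the family prefix.
#' @export
generate_families <- function(n_per_family, models,
                              alphabet = aa_alphabet()) {
  stopifnot(length(models) >= 2L,
            all(vapply(models, inherits, TRUE, "seq_model")))
  if (n_per_family == 0L) return(stats::setNames(character(0), character(0)))
  out <- character(0)
  for (f in seq_along(models)) {
    seqs <- simulate_proteins(models[[f]], n_per_family, alphabet)
    names(seqs) <- sprintf("fam%d_%d", f, seq_len(n_per_family))
    out <- c(out, seqs)
  }
  out
}
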