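#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Default residue ordering used for every index `i` in the encoding
#' (`A_1, ..., A_20`).  All pairwise distances are invariant to the
#' ordering as long as it is applied uniformly to every sequence; it is
#' configurable only so that encodings can be audited and reproduced.
#'
#' @return Character vector of the 20 one-letter amino-acid codes.
#' @export
#' @examples
#' aa_default_order()
aa_default_order <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Letters that are legal in FASTA protein records but are not one of the
# 20 standard residues: ambiguity codes, rare residues, gaps, stops.
NONSTANDARD_CHARS <- c("B", "J", "O", "U", "X", "Z", "-", ".", "*")

#' Amino-acid alphabet configuration
#'
#' Fixes the residue ordering `A_1, ..., A_20` used by the encoder and the
#' policy for characters outside the standard 20-letter alphabet.
#'
#' @param order Character vector of the 20 one-letter residue codes, a
#'   permutation of [aa_default_order()].  May also be given as a single
#'   20-character string.
#' @param nonstandard Policy for non-standard characters (B, J, O, U, X,
#'   Z, gaps, stops) found in input sequences: `"reject"` (default)
#'   raises an error naming the record and position; `"strip"` removes
#'   them with a warning and per-record removal count.
#' @return An object of class `aa_alphabet` with elements `order` and
#'   `nonstandard`.
#' @export
#' @examples
#' aa_alphabet()
#' aa_alphabet(nonstandard = "strip")
aa_alphabet <- function(order = aa_default_order(),
                        nonstandard = c("reject", "strip")) {
  if (is.character(order) && length(order) == 1L && nchar(order) == 20L)
    order <- strsplit(order, "")[[1]]
  order <- toupper(order)
  if (length(order) != 20L || anyDuplicated(order) ||
      !all(order %in% aa_default_order()))
    stop("`order` must be a permutation of the 20 standard one-letter ",
         "amino-acid codes", call. = FALSE)
  structure(
    list(order = order, nonstandard = match.arg(nonstandard)),
    class = "aa_alphabet"
  )
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("<aa_alphabet> order:", paste(x$order, collapse = ""),
      "| nonstandard:", x$nonstandard, "\n")
  invisible(x)
}

# Map residue characters of one sequence to 1..20 indices in `alphabet`.
# Stops if any character is unknown (validation happens upstream).
residue_indices <- function(residues, alphabet) {
  idx <- match(strsplit(residues, "")[[1]], alphabet$order)
  if (anyNA(idx))
    stop("sequence contains residues outside the configured alphabet",
         call. = FALSE)
  idx
}

#' Validate and normalise protein sequences
#'
#' Uppercases residue strings and applies the alphabet's
#' non-standard-residue policy.  Under `reject`, the first offending
#' character is reported with its record label and 1-based position;
#' under `strip`, offending characters are removed and a warning reports
#' the per-record removal counts.  Sequences must have length >= 2 after
#' normalisation (the encoding needs at least one adjacent pair).
#'
#' @param seqs Named character vector of residue strings.
#' @param alphabet An [aa_alphabet()].
#' @return Named character vector of validated sequences.
#' @export
validate_proteins <- function(seqs, alphabet = aa_alphabet()) {
  if (length(seqs) == 0L) stop("no sequences supplied", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence needs a non-empty label", call. = FALSE)
  seqs <- toupper(seqs)
  bad_re <- paste0("[^", paste(alphabet$order, collapse = ""), "]")
  stripped <- integer(0)
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[[k]], "")[[1]]
    bad <- which(!chars %in% alphabet$order)
    if (length(bad)) {
      if (alphabet$nonstandard == "reject")
        stop(sprintf(
          "record '%s': non-standard residue '%s' at position %d",
          names(seqs)[k], chars[bad[1]], bad[1]), call. = FALSE)
      seqs[[k]] <- gsub(bad_re, "", seqs[[k]])
      stripped[names(seqs)[k]] <- length(bad)
    }
    if (nchar(seqs[[k]]) < 2L)
      stop(sprintf("record '%s': sequence length %d < 2",
                   names(seqs)[k], nchar(seqs[[k]])), call. = FALSE)
  }
  if (length(stripped))
    warning(sprintf(
      "stripped non-standard residues: %s",
      paste(sprintf("%s (%d)", names(stripped), stripped), collapse = ", ")),
      call. = FALSE)
  seqs
}
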