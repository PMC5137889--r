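#' Read protein sequences from a FASTA file
#'
#' Parses with [Biostrings::readAAStringSet()], then uppercases and
#' validates every record against the alphabet (see
#' [validate_proteins()] for the non-standard-residue policy).
#' Record labels are the first whitespace-delimited token of each
#' header.
#'
#' @param path Path to a FASTA file.
#' @param alphabet An [aa_alphabet()].
#' @return Named character vector of validated residue strings.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "LLAL", ">s2", "AALL"), fa)
#' read_fasta(fa)
read_fasta <- function(path, alphabet = aa_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- grep("\\S", readLines(path, warn = FALSE))[1]
  if (is.na(first))
    stop("FASTA parse error: ", path, " is empty", call. = FALSE)
  if (!startsWith(trimws(readLines(path, warn = FALSE)[first]), ">"))
    stop("FASTA parse error at line ", first,
         ": expected a '>' header", call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e)
      stop("FASTA parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
  )
  if (length(set) == 0L)
    stop("FASTA parse error: no records in ", path, call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  validate_proteins(seqs, alphabet)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width for residue lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) == 0L) stop("no sequences to write", call. = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path, width = width)
  invisible(path)
}
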