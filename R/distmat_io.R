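#' Construct a validated distance matrix
#'
#' A distance matrix here is a plain numeric matrix with identical row
#' and column labels, non-negative entries, zero diagonal, and symmetry
#' within `tol`.  Entries are symmetrised (averaged) so downstream code
#' can rely on exact equality of `m[a, b]` and `m[b, a]`.
#'
#' @param values Square numeric matrix.
#' @param labels Sequence labels; defaults to the dimnames of `values`.
#' @param tol Maximum tolerated asymmetry, per cell.
#' @return Labeled symmetric numeric matrix.
#' @export
distance_matrix <- function(values, labels = rownames(values),
                            tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty distance matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop("distance matrix must be square, got ",
         nrow(values), "x", ncol(values), call. = FALSE)
  if (is.null(labels) || anyDuplicated(labels))
    stop("distance matrix needs unique labels", call. = FALSE)
  if (anyNA(values)) stop("distance matrix has missing cells", call. = FALSE)
  if (any(values < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(diag(values)) > tol))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(abs(values - t(values)) > tol))
    stop("distance matrix asymmetric beyond tolerance ", tol, call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  values
}

#' Write a distance matrix to CSV or PHYLIP
#'
#' CSV: a header row of labels, then one labeled row per sequence.
#' PHYLIP: the square distance-matrix dialect (a count line, then one
#' `label value...` row per sequence).  Cells are written with full
#' double precision unless `digits` is given, which rounds for display
#' only.
#'
#' @param m Distance matrix (see [distance_matrix()]).
#' @param path Output path.
#' @param format `"csv"` or `"phylip"`.
#' @param digits Optional display rounding; `NULL` keeps full precision.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("csv", "phylip"),
                                  digits = NULL) {
  format <- match.arg(format)
  m <- distance_matrix(m)
  fmt_cell <- function(x) {
    # %.17g round-trips doubles bit-identically; `digits` is display-only
    if (!is.null(digits)) sprintf("%.*f", digits, x)
    else sub("^(-?)(\\.)", "\\10\\2", sprintf("%.17g", x))
  }
  lines <- if (format == "csv") {
    c(paste(c("", rownames(m)), collapse = ","),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], vapply(m[i, ], fmt_cell, "")),
              collapse = ","), ""))
  } else {
    c(sprintf("%d", nrow(m)),
      vapply(seq_len(nrow(m)), function(i)
        paste(c(sprintf("%-10s", rownames(m)[i]),
                vapply(m[i, ], fmt_cell, "")),
              collapse = " "), ""))
  }
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}

#' Read a distance matrix from CSV or PHYLIP
#'
#' Accepts fully populated square matrices and the upper-triangular form
#' in which published tables are usually printed: missing lower-triangle
#' cells (empty CSV cells) are filled from the transpose, and a final
#' all-implied row omitted from the file is reconstructed.  A fully
#' populated matrix that is asymmetric beyond `1e-9` is rejected.
#'
#' @param path Input path.
#' @param format `"csv"` or `"phylip"`.
#' @return Labeled symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                          colClasses = NA)
    labels <- colnames(df)
    values <- suppressWarnings(
      matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
    row_labels <- rownames(df)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("PHYLIP format error: bad count line", call. = FALSE)
    if (length(lines) - 1L != n && length(lines) - 1L != n - 1L)
      stop("PHYLIP format error: expected ", n, " rows, found ",
           length(lines) - 1L, call. = FALSE)
    toks <- strsplit(trimws(lines[-1]), "\\s+")
    row_labels <- vapply(toks, `[`, "", 1L)
    values <- do.call(rbind, lapply(toks, function(tk) {
      v <- suppressWarnings(as.numeric(tk[-1]))
      length(v) <- n   # right-pad short (upper-triangular) rows with NA
      v
    }))
    labels <- if (length(row_labels) == n) row_labels else NULL
  }

  n <- length(labels)
  if (is.null(labels) || n < 2L)
    stop("format error: could not determine matrix labels", call. = FALSE)
  # Printed upper-triangular tables omit the final all-implied row.
  if (nrow(values) == n - 1L) {
    values <- rbind(values, rep(NA_real_, n))
    row_labels <- c(row_labels, labels[n])
  }
  if (nrow(values) != n)
    stop("format error: matrix is not square (", nrow(values), " rows, ",
         n, " columns)", call. = FALSE)
  if (!is.null(row_labels) && !identical(row_labels, labels) &&
      format == "csv")
    stop("format error: row labels do not match column labels",
         call. = FALSE)

  # An upper-triangular input may also leave the diagonal implicit.
  miss <- is.na(values)
  d <- diag(values)
  d[is.na(d)] <- 0
  diag(values) <- d
  fully_populated <- !any(miss[upper.tri(miss) | lower.tri(miss)])
  tv <- t(values)
  values[is.na(values)] <- tv[is.na(values)]
  if (anyNA(values))
    stop("format error: cell missing from both triangles", call. = FALSE)
  if (fully_populated && any(abs(values - t(values)) > 1e-9))
    stop("asymmetry beyond tolerance 1e-9 in a fully-populated matrix",
         call. = FALSE)
  distance_matrix(values, labels)
}
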