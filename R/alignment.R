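# Internal nucleotide coding: A=1, C=2, G=3, U=4, gap=5, anything else
# (IUPAC ambiguity codes, preserved verbatim in $chars) = 6.
NUC <- c("A", "C", "G", "U")
GAP_CODE <- 5L
AMBIG_CODE <- 6L

encode_chars <- function(ch) {
  code <- match(ch, c(NUC, "-"))
  code[is.na(code)] <- AMBIG_CODE
  code
}

normalize_rna <- function(x) {
  chartr("T.", "U-", toupper(x))
}

#' Construct an RNA alignment
#'
#' Builds the alignment container used throughout the package from either a
#' character vector of aligned sequences or a per-character matrix. Sequences
#' are normalized on input: letters are upper-cased, `T` becomes `U`, and `.`
#' becomes `-`. IUPAC ambiguity codes are preserved as given; downstream
#' statistics decide how to treat them (they never count as nucleotide
#' states).
#'
#' @param rows Character vector of aligned sequences (one string per
#'   sequence), or a character matrix with one row per sequence and one
#'   column per alignment column.
#' @param ids Sequence identifiers; defaults to `names(rows)` /
#'   `rownames(rows)`. Must be unique.
#' @return An object of class `rna_alignment`: a list with elements `ids`,
#'   `chars` (character matrix), `codes` (integer matrix, A=1 C=2 G=3 U=4
#'   gap=5 ambiguous=6), `n_sequences` and `n_columns`.
#' @examples
#' aln <- rna_alignment(c(s1 = "ACGU", s2 = "AC-U"))
#' aln$n_columns
#' @export
rna_alignment <- function(rows, ids = NULL) {
  if (is.matrix(rows)) {
    if (is.null(ids)) ids <- rownames(rows)
    chars <- matrix(normalize_rna(rows), nrow = nrow(rows))
  } else {
    if (is.null(ids)) ids <- names(rows)
    rows <- normalize_rna(rows)
    widths <- nchar(rows)
    if (length(unique(widths)) > 1L) {
      bad <- which(widths != widths[1L])[1L]
      stop("ragged alignment: record ", if (!is.null(ids)) ids[bad] else bad,
           " has width ", widths[bad], ", expected ", widths[1L])
    }
    chars <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(rows), byrow = TRUE)
  }
  if (nrow(chars) < 2L) stop("an alignment needs at least 2 sequences")
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(chars)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  codes <- matrix(encode_chars(chars), nrow = nrow(chars))
  rownames(chars) <- rownames(codes) <- ids
  structure(
    list(ids = ids, chars = chars, codes = codes,
         n_sequences = nrow(chars), n_columns = ncol(chars)),
    class = "rna_alignment"
  )
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("RNA alignment:", x$n_sequences, "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads an aligned FASTA file into an [rna_alignment()]. Normalization
#' (upper case, `T`->`U`, `.`->`-`) is applied; all records must have the
#' same length after normalization.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `rna_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  rows <- as.character(set)
  names(rows) <- sub("\\s.*$", "", names(rows))
  aln <- rna_alignment(rows)
  message("read_alignment: ", aln$n_sequences, " sequences, ",
          aln$n_columns, " columns")
  aln
}

#' Write an alignment as FASTA
#'
#' @param alignment An `rna_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  rows <- apply(alignment$chars, 1L, paste, collapse = "")
  out <- character(2L * length(rows))
  out[c(TRUE, FALSE)] <- paste0(">", alignment$ids)
  out[c(FALSE, TRUE)] <- rows
  writeLines(out, path)
  invisible(path)
}

#' Map alignment columns to reference-sequence positions
#'
#' Columns where the reference sequence carries a base (anything except `-`)
#' map to consecutive 1-based reference positions; columns gapped in the
#' reference map to `NA`. All of the package's reports use this map to
#' translate alignment columns into the reference (crystal-structure)
#' numbering.
#'
#' @param alignment An `rna_alignment`.
#' @param reference_sequence_id Identifier of the reference sequence, which
#'   must be present in the alignment.
#' @return An object of class `position_map` with `column_to_position`
#'   (integer vector, `NA` for reference-gapped columns) and
#'   `position_to_column` (its inverse).
#' @export
build_position_map <- function(alignment, reference_sequence_id) {
  idx <- match(reference_sequence_id, alignment$ids)
  if (is.na(idx)) stop("reference sequence not in alignment: ",
                       reference_sequence_id)
  ref <- alignment$chars[idx, ]
  has_base <- ref != "-"
  col_to_pos <- rep(NA_integer_, alignment$n_columns)
  col_to_pos[has_base] <- seq_len(sum(has_base))
  structure(
    list(reference_sequence_id = reference_sequence_id,
         column_to_position = col_to_pos,
         position_to_column = which(has_base)),
    class = "position_map"
  )
}

#' Translate alignment columns to reference positions
#'
#' @param map A `position_map`.
#' @param columns Integer vector of alignment columns.
#' @return Integer vector of reference positions (`NA` where the reference is
#'   gapped).
#' @export
columns_to_positions <- function(map, columns) {
  map$column_to_position[columns]
}

#' Count unordered column pairs
#'
#' Number of unordered pairs among `n` alignment columns, i.e. the size of
#' the all-against-all comparison an unfiltered covariation scan would face.
#'
#' @param n Number of columns.
#' @return `n * (n - 1) / 2`.
#' @export
n_column_pairs <- function(n) {
  n * (n - 1) / 2
}

#' Enumerate unordered column pairs
#'
#' @param n Number of columns.
#' @return Two-column integer matrix of all pairs `(i, j)` with `i < j`.
#' @export
column_pairs <- function(n) {
  stopifnot(n >= 2)
  n <- as.integer(n)
  cbind(col_i = rep.int(seq_len(n - 1L), times = (n - 1L):1L),
        col_j = sequence((n - 1L):1L, from = 2:n))
}
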