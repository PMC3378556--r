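# Frequency-based column statistics: conservation entropy, pair-state
# tables, MIxy, MIp (+Z), OMES.

#' Per-column nucleotide profile and conservation entropy
#'
#' Computes nucleotide and gap frequencies for one alignment column and its
#' Shannon conservation entropy over the five states A, C, G, U and gap:
#' `H = -sum_i Pi log2 Pi - Pgap log2 Pgap`, zero-frequency terms
#' contributing 0. Ambiguity codes are excluded from the frequencies and
#' from the denominator. Low entropy means a conserved column.
#'
#' @param alignment An `rna_alignment`.
#' @param column Column index (1-based).
#' @return An object of class `column_profile`: list with `freqs` (named
#'   A/C/G/U proportions), `gap_freq`, `entropy` (bits) and `n_effective`.
#' @export
column_profile <- function(alignment, column) {
  stopifnot(column >= 1, column <= alignment$n_columns)
  code <- alignment$codes[, column]
  cnt <- tabulate(code[code <= GAP_CODE], nbins = GAP_CODE)
  n <- sum(cnt)
  if (n == 0L) {
    warning("column ", column, " holds only ambiguity codes")
    freqs <- stats::setNames(rep(0, 4), NUC)
    return(structure(list(freqs = freqs, gap_freq = 0, entropy = 0,
                          n_effective = 0L), class = "column_profile"))
  }
  p <- cnt / n
  structure(
    list(freqs = stats::setNames(p[1:4], NUC), gap_freq = p[5L],
         entropy = shannon_bits(p), n_effective = n),
    class = "column_profile"
  )
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conservation entropies for all columns
#'
#' Vectorized [column_profile()] entropy over every alignment column; used
#' by the coarse filter.
#'
#' @param alignment An `rna_alignment`.
#' @return Numeric vector of per-column entropies (bits).
#' @export
column_entropies <- function(alignment) {
  vapply(seq_len(alignment$n_columns), function(j) {
    code <- alignment$codes[, j]
    cnt <- tabulate(code[code <= GAP_CODE], nbins = GAP_CODE)
    n <- sum(cnt)
    if (n == 0L) 0 else shannon_bits(cnt / n)
  }, numeric(1))
}

#' Joint base-pair-type table for a column pair
#'
#' Counts ordered nucleotide pairs (M, N) over the sequences that carry an
#' unambiguous state at both columns. By default only A/C/G/U states
#' contribute (base-pair covariation is defined on nucleotides); with
#' `include_gap = TRUE` the gap is counted as a fifth state.
#'
#' @param alignment An `rna_alignment`.
#' @param col_x,col_y Distinct column indices.
#' @param include_gap Count the gap as a state?
#' @return An object of class `pair_state_table`: `counts` (4x4 or 5x5
#'   matrix, rows = `col_x` state, columns = `col_y` state), `joint_freqs`,
#'   `marginal_x`, `marginal_y`, `n_effective`, `n_total`.
#' @export
pair_state_table <- function(alignment, col_x, col_y, include_gap = FALSE) {
  stopifnot(col_x != col_y)
  x <- alignment$codes[, col_x]
  y <- alignment$codes[, col_y]
  kmax <- if (include_gap) GAP_CODE else 4L
  ok <- x <= kmax & y <= kmax
  states <- if (include_gap) c(NUC, "-") else NUC
  k <- length(states)
  cnt <- matrix(tabulate((y[ok] - 1L) * k + x[ok], nbins = k * k),
                nrow = k, dimnames = list(states, states))
  # tabulate fills column-major: index (y-1)*k + x puts x in rows
  pair_state_table_from_counts(cnt, n_total = alignment$n_sequences)
}

#' Build a pair-state table from a count matrix
#'
#' @param counts Square count matrix with nucleotide (optionally gap)
#'   dimnames; rows are the 5' state, columns the 3' state.
#' @param n_total Total sequences in the source alignment (defaults to
#'   `sum(counts)`).
#' @return A `pair_state_table`.
#' @export
pair_state_table_from_counts <- function(counts, n_total = sum(counts)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(dimnames(counts))) {
    states <- c(NUC, "-")[seq_len(nrow(counts))]
    dimnames(counts) <- list(states, states)
  }
  n <- sum(counts)
  joint <- if (n > 0) counts / n else counts
  structure(
    list(counts = counts, joint_freqs = joint,
         marginal_x = rowSums(joint), marginal_y = colSums(joint),
         n_effective = n, n_total = n_total),
    class = "pair_state_table"
  )
}

#' Mutual information between two columns (MIxy)
#'
#' `MIxy = sum_{M,N} Pr(M,N) log2( Pr(M,N) / (Pr(M) Pr(N)) )` over the
#' nucleotide pair types of a [pair_state_table()]; zero-probability terms
#' contribute 0. Units are bits.
#'
#' @param table A `pair_state_table`.
#' @return MIxy in bits, or `NA` (with a warning) when fewer than 2
#'   sequences contribute.
#' @export
mixy <- function(table) {
  if (table$n_effective < 2L) {
    warning("fewer than 2 contributing sequences; MIxy undefined")
    return(NA_real_)
  }
  p <- table$joint_freqs
  e <- outer(table$marginal_x, table$marginal_y)
  nz <- p > 0
  max(sum(p[nz] * log2(p[nz] / e[nz])), 0)
}

#' OMES score for a column pair
#'
#' Observed-minus-expected-squared statistic:
#' `OMES = sum_cells (N0 - Ne)^2 / Nt` with `Ne` the product of marginal
#' counts over `Nt`, summed over all 16 dinucleotide cells (observed or
#' not). Zero for perfectly independent columns.
#'
#' @param table A `pair_state_table`.
#' @return OMES score (>= 0), or `NA` with a warning when fewer than 2
#'   sequences contribute.
#' @export
omes <- function(table) {
  if (table$n_effective < 2L) {
    warning("fewer than 2 contributing sequences; OMES undefined")
    return(NA_real_)
  }
  n0 <- table$counts
  nt <- table$n_effective
  ne <- outer(rowSums(n0), colSums(n0)) / nt
  sum((n0 - ne)^2) / nt
}

#' Sparse symmetric score container
#'
#' Wraps a `(col_i, col_j, score)` table as the score-matrix object consumed
#' by the N-Best machinery. Pairs are stored once with `col_i < col_j`;
#' scores are symmetric by construction.
#'
#' @param pairs Data frame (or matrix) with columns `col_i`, `col_j` and a
#'   score column.
#' @param method Score name, e.g. `"CPE"`, `"MIxy"`, `"MIp"`, `"OMES"`.
#' @param score Name of the score column in `pairs` (default `"score"`).
#' @return A data frame of class `score_matrix` with columns `col_i`,
#'   `col_j`, `score`, ordered by (`col_i`, `col_j`), and a `method`
#'   attribute.
#' @export
score_matrix <- function(pairs, method = "score", score = "score") {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("col_i", "col_j", score) %in% names(pairs)))
  df <- data.frame(col_i = pmin(pairs$col_i, pairs$col_j),
                   col_j = pmax(pairs$col_i, pairs$col_j),
                   score = pairs[[score]])
  if (any(df$col_i == df$col_j)) stop("self-pairs are not allowed")
  if (anyDuplicated(df[c("col_i", "col_j")])) {
    stop("duplicate column pairs in score matrix")
  }
  df <- df[order(df$col_i, df$col_j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("score_matrix", "data.frame"), method = method)
}

#' Compute MIxy for a set of column pairs
#'
#' Workhorse used by the coarse filter and the pipeline: MIxy for every
#' requested pair (or all unordered pairs when `pairs` is `NULL`).
#'
#' @param alignment An `rna_alignment`.
#' @param pairs Optional two-column matrix/data.frame of column pairs.
#' @return A `score_matrix` of MIxy values (`NA` for pairs with fewer than 2
#'   contributing sequences).
#' @export
mixy_scores <- function(alignment, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- column_pairs(alignment$n_columns)
  }
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  codes <- alignment$codes
  scores <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    x <- codes[, pairs[r, 1L]]
    y <- codes[, pairs[r, 2L]]
    ok <- x <= 4L & y <= 4L
    cnt <- tabulate((y[ok] - 1L) * 4L + x[ok], nbins = 16L)
    scores[r] <- mi_from_counts16(cnt)
  }
  score_matrix(data.frame(col_i = pairs[, 1L], col_j = pairs[, 2L],
                          score = scores), method = "MIxy")
}

mi_from_counts16 <- function(cnt) {
  n <- sum(cnt)
  if (n < 2L) return(NA_real_)
  p <- matrix(cnt / n, nrow = 4L)
  e <- outer(rowSums(p), colSums(p))
  nz <- p > 0
  max(sum(p[nz] * log2(p[nz] / e[nz])), 0)
}

#' Average-product-corrected mutual information (MIp) and its Z-score
#'
#' Removes the background mutual information shared by high-entropy columns:
#' `MIp(a,b) = MIxy(a,b) - APC(a,b)` with
#' `APC(a,b) = mean_MI(a,.) * mean_MI(.,b) / overall_mean_MI`, all means
#' taken over the scored pair set. The Z-score standardizes MIp over that
#' same set.
#'
#' @param scores A `score_matrix` of MIxy values (pairs with `NA` scores are
#'   dropped with a message).
#' @param z Also compute the Z-score? Set `FALSE` when the MIp spread is
#'   degenerate (zero standard deviation raises an error for the Z-score).
#' @return Data frame with columns `col_i`, `col_j`, `mixy`, `apc`, `mip`
#'   and (when `z = TRUE`) `mip_z`.
#' @export
mip <- function(scores, z = TRUE) {
  df <- as.data.frame(scores)
  drop <- is.na(df$score)
  if (any(drop)) {
    message("mip: dropping ", sum(drop), " pair(s) with undefined MIxy")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no scored pairs for MIp")
  cols <- sort(unique(c(df$col_i, df$col_j)))
  sum_mi <- stats::setNames(numeric(length(cols)), cols)
  n_mi <- stats::setNames(numeric(length(cols)), cols)
  ci <- as.character(df$col_i); cj <- as.character(df$col_j)
  for (r in seq_len(nrow(df))) {
    sum_mi[ci[r]] <- sum_mi[ci[r]] + df$score[r]
    sum_mi[cj[r]] <- sum_mi[cj[r]] + df$score[r]
    n_mi[ci[r]] <- n_mi[ci[r]] + 1
    n_mi[cj[r]] <- n_mi[cj[r]] + 1
  }
  mean_mi <- sum_mi / n_mi
  overall <- mean(df$score)
  if (overall == 0) {
    warning("overall mean MIxy is 0; all MIp set to 0")
    apc <- rep(0, nrow(df))
  } else {
    apc <- mean_mi[ci] * mean_mi[cj] / overall
  }
  out <- data.frame(col_i = df$col_i, col_j = df$col_j, mixy = df$score,
                    apc = unname(apc), mip = df$score - unname(apc))
  if (z) {
    s <- stats::sd(out$mip)
    if (is.na(s) || s == 0) {
      stop("MIp standard deviation is 0; Z-score undefined ",
           "(call mip(..., z = FALSE) for the uncorrected scores)")
    }
    out$mip_z <- (out$mip - mean(out$mip)) / s
  }
  rownames(out) <- NULL
  out
}

#' Write a score matrix as TSV
#'
#' Columns: `col_i`, `col_j`, `ref_pos_i`, `ref_pos_j`, `method`, `score`,
#' in deterministic (`col_i`, `col_j`) order.
#'
#' @param scores A `score_matrix`.
#' @param path Output path.
#' @param position_map Optional `position_map` for reference numbering.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, position_map = NULL) {
  df <- as.data.frame(scores)
  df$ref_pos_i <- if (is.null(position_map)) NA_integer_ else
    columns_to_positions(position_map, df$col_i)
  df$ref_pos_j <- if (is.null(position_map)) NA_integer_ else
    columns_to_positions(position_map, df$col_j)
  df$method <- attr(scores, "method")
  utils::write.table(
    df[c("col_i", "col_j", "ref_pos_i", "ref_pos_j", "method", "score")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
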