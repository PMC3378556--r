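# Candidate generation (entropy/MI coarse filter) and significance calling
# (Joint N-Best, one-directional N-Best, merging of call sets).

# Per-column best/second-best partner over a score matrix. Ties for the
# best partner break toward the lower column index (deterministic).
per_column_best <- function(scores) {
  df <- as.data.frame(scores)
  long <- data.frame(col = c(df$col_i, df$col_j),
                     partner = c(df$col_j, df$col_i),
                     score = c(df$score, df$score))
  long <- long[!is.na(long$score), , drop = FALSE]
  long <- long[order(long$col, -long$score, long$partner), , drop = FALSE]
  first <- !duplicated(long$col)
  res <- long[first, , drop = FALSE]
  names(res) <- c("col", "best_partner", "best_score")
  rest <- long[!first, , drop = FALSE]
  second <- rest[!duplicated(rest$col), c("col", "score")]
  res$second_score <- second$score[match(res$col, second$col)]
  res$second_score[is.na(res$second_score)] <- 0
  res$ratio <- ifelse(res$best_score > 0, res$second_score / res$best_score,
                      NA_real_)
  res$single_partner <- !(res$col %in% rest$col)
  rownames(res) <- NULL
  res
}

#' One-directional N-Best ratio for a column
#'
#' Ratio of the second-highest to the highest covariation score among a
#' column's scored partners. Low values mean one partner dominates (an
#' unambiguous base-pair signal); values near 1 mean the covariation is
#' shared across partners. A column with a single partner gets ratio 0
#' (no competitor).
#'
#' @param scores A `score_matrix`.
#' @param col Column index with at least one scored partner.
#' @return The ratio in `[0, 1]`, or `NA` when the best score is not
#'   positive.
#' @export
one_directional_nbest <- function(scores, col) {
  tab <- per_column_best(scores)
  row <- match(col, tab$col)
  if (is.na(row)) stop("column ", col, " has no scored partners")
  tab$ratio[row]
}

#' Joint N-Best base-pair calling
#'
#' For every scored pair (X, Y) computes both one-directional N-Best ratios.
#' The pair is called (`passed`) when Y is X's best-scoring partner and X is
#' Y's (mutual best), and both ratios are at or below the threshold. Pairs
#' whose best score is not positive are flagged not callable.
#'
#' @param scores A `score_matrix` (CPE, MIxy, MIp, ...).
#' @param threshold N-Best ratio threshold in `(0, 1]`; default 0.5.
#' @return Data frame with columns `col_i`, `col_j`, `score`, `nbest_i`,
#'   `nbest_j`, `mutual_best`, `callable`, `single_partner_i/j`, `passed`.
#' @export
joint_nbest <- function(scores, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  df <- as.data.frame(scores)
  df <- df[!is.na(df$score), , drop = FALSE]
  tab <- per_column_best(scores)
  i <- match(df$col_i, tab$col)
  j <- match(df$col_j, tab$col)
  nbest_i <- tab$ratio[i]
  nbest_j <- tab$ratio[j]
  mutual <- tab$best_partner[i] == df$col_j & tab$best_partner[j] == df$col_i
  callable <- !is.na(nbest_i) & !is.na(nbest_j)
  passed <- callable & mutual & nbest_i <= threshold & nbest_j <= threshold
  out <- data.frame(col_i = df$col_i, col_j = df$col_j, score = df$score,
                    nbest_i = nbest_i, nbest_j = nbest_j,
                    mutual_best = mutual, callable = callable,
                    single_partner_i = tab$single_partner[i],
                    single_partner_j = tab$single_partner[j],
                    passed = passed)
  attr(out, "method") <- attr(scores, "method")
  attr(out, "threshold") <- threshold
  rownames(out) <- NULL
  out
}

#' Entropy / mutual-information coarse filter
#'
#' Pre-selects the column pairs worth scoring with the expensive
#' event-counting scan. A pair (X, Y) survives when (1) the absolute
#' difference of the two columns' conservation entropies is at most
#' `entropy_tol` (positions with similar conservation are the ones able to
#' covary) and (2) MIxy(X, Y) ranks within the top `top_k` of X's partner
#' scores and within the top `top_k` of Y's.
#'
#' @param alignment An `rna_alignment`.
#' @param entropy_tol Entropy-difference tolerance in bits (default 0.2).
#' @param top_k Per-column MI rank cutoff (default 100).
#' @return Data frame with columns `col_i`, `col_j`, `H_i`, `H_j`, `mixy`,
#'   sorted by (`col_i`, `col_j`).
#' @export
coarse_filter <- function(alignment, entropy_tol = 0.2, top_k = 100) {
  stopifnot(entropy_tol >= 0, top_k >= 1)
  H <- column_entropies(alignment)
  mi <- mixy_scores(alignment)
  df <- as.data.frame(mi)
  ok_mi <- !is.na(df$score)
  # per-column rank of each pair's MI among that column's partners
  long <- data.frame(col = c(df$col_i, df$col_j),
                     pair = rep(seq_len(nrow(df)), 2L),
                     score = c(df$score, df$score))
  long <- long[!is.na(long$score), , drop = FALSE]
  rk <- stats::ave(-long$score, long$col,
                   FUN = function(s) rank(s, ties.method = "min"))
  in_top <- rk <= top_k
  top_count <- tapply(in_top, long$pair, sum)
  both_top <- rep(FALSE, nrow(df))
  both_top[as.integer(names(top_count))] <- top_count == 2L
  keep <- ok_mi & both_top & abs(H[df$col_i] - H[df$col_j]) <= entropy_tol
  out <- data.frame(col_i = df$col_i[keep], col_j = df$col_j[keep],
                    H_i = H[df$col_i[keep]], H_j = H[df$col_j[keep]],
                    mixy = df$score[keep])
  out <- out[order(out$col_i, out$col_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two call sets with provenance
#'
#' Set union of two base-pair call lists (alignment-column coordinates),
#' tagging each pair with its source(s).
#'
#' @param calls_a,calls_b Data frames with `col_i`, `col_j` columns.
#' @param labels Length-2 character vector naming the two sources.
#' @return Data frame `col_i`, `col_j`, `provenance` (`"a_only"`,
#'   `"b_only"`, `"both"` with `labels` substituted), sorted.
#' @export
merge_calls <- function(calls_a, calls_b, labels = c("a", "b")) {
  key <- function(d) paste(pmin(d$col_i, d$col_j), pmax(d$col_i, d$col_j))
  a <- unique(data.frame(col_i = pmin(calls_a$col_i, calls_a$col_j),
                         col_j = pmax(calls_a$col_i, calls_a$col_j)))
  b <- unique(data.frame(col_i = pmin(calls_b$col_i, calls_b$col_j),
                         col_j = pmax(calls_b$col_i, calls_b$col_j)))
  all <- unique(rbind(a, b))
  in_a <- key(all) %in% key(a)
  in_b <- key(all) %in% key(b)
  all$provenance <- ifelse(in_a & in_b, "both",
                           ifelse(in_a, paste0(labels[1L], "_only"),
                                  paste0(labels[2L], "_only")))
  all <- all[order(all$col_i, all$col_j), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Called pairs from a Joint N-Best result
#'
#' @param nbest A [joint_nbest()] result.
#' @return Data frame of the passed pairs (`col_i`, `col_j`, `score`).
#' @export
nbest_calls <- function(nbest) {
  out <- nbest[nbest$passed, c("col_i", "col_j", "score"), drop = FALSE]
  rownames(out) <- NULL
  out
}
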