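# Helix extension from nucleation pairs, purity / GU-plus purity scoring,
# neighbor-effect identification with 3-D distances, and evaluation of
# calls against a reference structure.

CANONICAL_TYPES <- c("A:U", "U:A", "G:C", "C:G")
WOBBLE_TYPES <- c("G:U", "U:G")
# integer pair-type codes of the canonical + wobble set (see pec.R coding)
CANONICAL_CODES <- c(4L, 13L, 10L, 7L, 12L, 15L)

#' Fraction of sequences forming a canonical pair at two columns
#'
#' Fraction of sequences whose states at the two columns form a
#' Watson-Crick or wobble pair (G:C, C:G, A:U, U:A, G:U, U:G), computed
#' over the sequences carrying an unambiguous, ungapped state at both
#' columns.
#'
#' @param alignment An `rna_alignment`.
#' @param col_i,col_j Column indices.
#' @return List with `fraction` (0 when no sequence qualifies) and `n`
#'   (denominator).
#' @export
canonical_pair_fraction <- function(alignment, col_i, col_j) {
  x <- alignment$codes[, col_i]
  y <- alignment$codes[, col_j]
  ok <- x <= 4L & y <= 4L
  n <- sum(ok)
  if (n == 0L) return(list(fraction = 0, n = 0L))
  t <- (x[ok] - 1L) * 4L + y[ok]
  list(fraction = mean(t %in% CANONICAL_CODES), n = n)
}

#' Extend helices from covariation-supported nucleation pairs
#'
#' Starting from each nucleation pair (i, j), iteratively adds the adjacent
#' antiparallel pairs (i-1, j+1) (outward) and (i+1, j-1) (inward) while
#' the canonical-pair fraction at the candidate columns is at least
#' `canonical_fraction`; extension stops in a direction at the first
#' failure, at the alignment edge, or when the candidate is already
#' accepted. This recovers conserved base pairs that cannot covary because
#' they barely vary. Extended pairs that would reuse a nucleation column
#' are dropped; when two extensions claim the same column the higher
#' canonical fraction wins.
#'
#' @param alignment An `rna_alignment`.
#' @param nucleation_pairs Data frame/matrix of pairs (`col_i`, `col_j`).
#' @param canonical_fraction Acceptance threshold (default 0.85).
#' @return An object of class `helix_extension`: `nucleation` (data frame),
#'   `extended` (data frame `col_i`, `col_j`, `canonical_fraction`,
#'   `direction`, `origin_i`, `origin_j`), `conflicts` (dropped pairs).
#' @export
helix_extend <- function(alignment, nucleation_pairs,
                         canonical_fraction = 0.85) {
  np <- as.data.frame(nucleation_pairs)[, 1:2]
  names(np) <- c("col_i", "col_j")
  np <- unique(data.frame(col_i = pmin(np$col_i, np$col_j),
                          col_j = pmax(np$col_i, np$col_j)))
  np <- np[order(np$col_i, np$col_j), , drop = FALSE]
  n_col <- alignment$n_columns
  accepted <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(np))) {
    assign(paste(np$col_i[r], np$col_j[r]), TRUE, envir = accepted)
  }
  ext <- list()
  for (r in seq_len(nrow(np))) {
    for (dir in list(c(-1L, 1L, "outward"), c(1L, -1L, "inward"))) {
      di <- as.integer(dir[1L]); dj <- as.integer(dir[2L])
      ci <- np$col_i[r] + di
      cj <- np$col_j[r] + dj
      while (ci >= 1L && cj <= n_col && ci < cj) {
        key <- paste(ci, cj)
        if (exists(key, envir = accepted, inherits = FALSE)) break
        f <- canonical_pair_fraction(alignment, ci, cj)
        if (f$fraction < canonical_fraction) break
        assign(key, TRUE, envir = accepted)
        ext[[length(ext) + 1L]] <- data.frame(
          col_i = ci, col_j = cj, canonical_fraction = f$fraction,
          direction = dir[3L], origin_i = np$col_i[r], origin_j = np$col_j[r])
        ci <- ci + di
        cj <- cj + dj
      }
    }
  }
  ext <- if (length(ext)) do.call(rbind, ext) else
    data.frame(col_i = integer(0), col_j = integer(0),
               canonical_fraction = numeric(0), direction = character(0),
               origin_i = integer(0), origin_j = integer(0))
  # resolve column conflicts: nucleation columns win, then higher fraction
  nuc_cols <- unique(c(np$col_i, np$col_j))
  conflicts <- ext[ext$col_i %in% nuc_cols | ext$col_j %in% nuc_cols, ,
                   drop = FALSE]
  ext <- ext[!(ext$col_i %in% nuc_cols | ext$col_j %in% nuc_cols), ,
             drop = FALSE]
  ext <- ext[order(-ext$canonical_fraction, ext$col_i, ext$col_j), ,
             drop = FALSE]
  used <- integer(0)
  keep <- logical(nrow(ext))
  for (r in seq_len(nrow(ext))) {
    cols <- c(ext$col_i[r], ext$col_j[r])
    if (!any(cols %in% used)) {
      keep[r] <- TRUE
      used <- c(used, cols)
    }
  }
  conflicts <- rbind(conflicts, ext[!keep, , drop = FALSE])
  if (nrow(conflicts)) {
    message("helix_extend: ", nrow(conflicts),
            " extended pair(s) dropped in column conflicts")
  }
  ext <- ext[keep, , drop = FALSE]
  ext <- ext[order(ext$col_i, ext$col_j), , drop = FALSE]
  rownames(ext) <- rownames(conflicts) <- NULL
  structure(list(nucleation = np, extended = ext, conflicts = conflicts),
            class = "helix_extension")
}

#' Base-pair purity and GU-plus purity
#'
#' Measures how exclusively each nucleotide at two columns partners with a
#' single nucleotide at the other. Pair types are ranked by frequency
#' (ties lexicographic); the top type is accepted, and each further type is
#' accepted only if both its 5' and its 3' nucleotide are unused by every
#' already-accepted type — i.e. it covaries (both symbols change) with all
#' of them. Purity is the summed frequency of accepted types. The GU-plus
#' variant additionally credits the wobble pairs G:U/U:G alongside accepted
#' canonical pairs (G:C/C:G, A:U/U:A): wobble and canonical types neither
#' block nor are blocked by one another.
#'
#' @param table A `pair_state_table` (nucleotide states; gap-free), or a
#'   4x4 count matrix.
#' @return An object of class `purity_result`: `purity`, `gu_plus_purity`,
#'   `ranked` (data frame of types, frequencies and acceptance flags).
#' @export
purity <- function(table) {
  if (is.matrix(table)) table <- pair_state_table_from_counts(table)
  cnt <- table$counts[NUC, NUC]
  total <- sum(cnt)
  if (total == 0) stop("empty pair-state table; purity undefined")
  freq <- cnt / total
  types <- as.vector(outer(NUC, NUC, function(a, b) paste0(a, ":", b)))
  f <- as.vector(freq)  # column-major: matches outer() order
  present <- f > 0
  df <- data.frame(type = types[present], freq = f[present])
  df <- df[order(-df$freq, df$type), , drop = FALSE]
  walk <- function(gu_plus) {
    accepted <- character(0)
    take <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      cand <- df$type[r]
      blocked <- FALSE
      for (acc in accepted) {
        if (gu_plus && gu_exempt(cand, acc)) next
        if (substr(cand, 1L, 1L) == substr(acc, 1L, 1L) ||
            substr(cand, 3L, 3L) == substr(acc, 3L, 3L)) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) {
        accepted <- c(accepted, cand)
        take[r] <- TRUE
      }
    }
    take
  }
  acc_base <- walk(FALSE)
  acc_gu <- walk(TRUE)
  df$accepted <- acc_base
  df$accepted_gu_plus <- acc_gu
  rownames(df) <- NULL
  structure(
    list(purity = sum(df$freq[acc_base]),
         gu_plus_purity = sum(df$freq[acc_gu]),
         ranked = df),
    class = "purity_result"
  )
}

# wobble vs canonical-or-wobble pairs are mutually exempt from blocking
gu_exempt <- function(a, b) {
  cw <- c(CANONICAL_TYPES, WOBBLE_TYPES)
  (a %in% WOBBLE_TYPES && b %in% cw) || (b %in% WOBBLE_TYPES && a %in% cw)
}

#' @export
print.purity_result <- function(x, ...) {
  cat("purity:", format(x$purity, digits = 4),
      " GU-plus:", format(x$gu_plus_purity, digits = 4), "\n")
  invisible(x)
}

#' Identify neighbor effects
#'
#' Flags column pairs with significant but non-exclusive covariation: the
#' pair's one-directional N-Best ratio (the larger of the two columns')
#' is at least `ratio_min` (the covariation is shared with competitors),
#' CPE is at least `cpe_min`, and the pair accumulated at least
#' `events_min` total events. Pairs already called as base pairs are
#' excluded. Such pairs rarely base-pair but their nucleotides are
#' typically close in the 3-D structure, so each flagged pair is annotated
#' with the base-center distance and the reference-structure class when a
#' structure is available.
#'
#' @param pec A `pec_result` from [pec_scan()].
#' @param called_pairs Optional data frame of already-called base pairs
#'   (`col_i`, `col_j`) removed from candidacy.
#' @param structure Optional `reference_structure` for distance/class
#'   annotation.
#' @param position_map Optional `position_map` (required with `structure`).
#' @param ratio_min,cpe_min,events_min Thresholds; defaults 0.85, 0.25, 10.
#' @return Data frame with `col_i`, `col_j`, `ref_pos_i`, `ref_pos_j`,
#'   `cpe`, `nbest_ratio`, `total_events`, `distance`, `h_bonded_class`.
#' @export
neighbor_effects <- function(pec, called_pairs = NULL, structure = NULL,
                             position_map = NULL, ratio_min = 0.85,
                             cpe_min = 0.25, events_min = 10) {
  scores <- cpe_scores(pec)
  tab <- per_column_best(scores)
  df <- as.data.frame(scores)
  retained <- pec[!pec$excluded & !is.na(pec$cpe), , drop = FALSE]
  ratio_i <- tab$ratio[match(df$col_i, tab$col)]
  ratio_j <- tab$ratio[match(df$col_j, tab$col)]
  ratio <- pmax(ratio_i, ratio_j)
  total <- retained$total_events[match(paste(df$col_i, df$col_j),
                                       paste(retained$col_i, retained$col_j))]
  keep <- !is.na(ratio) & ratio >= ratio_min & df$score >= cpe_min &
    total >= events_min
  if (!is.null(called_pairs) && nrow(called_pairs)) {
    key <- paste(pmin(called_pairs$col_i, called_pairs$col_j),
                 pmax(called_pairs$col_i, called_pairs$col_j))
    keep <- keep & !(paste(df$col_i, df$col_j) %in% key)
  }
  out <- data.frame(col_i = df$col_i[keep], col_j = df$col_j[keep],
                    cpe = df$score[keep], nbest_ratio = ratio[keep],
                    total_events = total[keep])
  if (!is.null(position_map)) {
    out$ref_pos_i <- columns_to_positions(position_map, out$col_i)
    out$ref_pos_j <- columns_to_positions(position_map, out$col_j)
  } else {
    out$ref_pos_i <- rep(NA_integer_, nrow(out))
    out$ref_pos_j <- rep(NA_integer_, nrow(out))
  }
  out$distance <- rep(NA_real_, nrow(out))
  if (!is.null(structure) && !is.null(structure$base_centers)) {
    ok <- !is.na(out$ref_pos_i) & !is.na(out$ref_pos_j)
    out$distance[ok] <- vapply(which(ok), function(r) {
      suppressWarnings(
        base_center_distance(structure, out$ref_pos_i[r], out$ref_pos_j[r]))
    }, numeric(1))
  }
  out$h_bonded_class <- structure_pair_class(structure, out$ref_pos_i,
                                             out$ref_pos_j)
  out <- out[order(out$col_i, out$col_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate base-pair calls against a reference structure
#'
#' Maps each called column pair to reference positions and labels it a true
#' positive when the position pair is annotated in the reference structure
#' (secondary or tertiary), a false positive otherwise. Calls on columns
#' gapped in the reference are reported unmappable and excluded from the
#' counts. When a `score` column is present, calls are ranked by it
#' (descending) for the precision-of-top-N curve.
#'
#' @param calls Data frame with `col_i`, `col_j` and optionally `score`.
#' @param position_map A `position_map` for the structure's reference
#'   sequence.
#' @param structure A `reference_structure`.
#' @return An object of class `call_evaluation`: `per_call` (data frame
#'   with `tp`, `class`, `mappable`), `summary` (counts and precision),
#'   `topn` (data frame `N`, `precision`).
#' @export
evaluate_calls <- function(calls, position_map, structure) {
  calls <- as.data.frame(calls)
  out <- data.frame(col_i = calls$col_i, col_j = calls$col_j)
  out$score <- if ("score" %in% names(calls)) calls$score else NA_real_
  out$ref_pos_i <- columns_to_positions(position_map, out$col_i)
  out$ref_pos_j <- columns_to_positions(position_map, out$col_j)
  out$mappable <- !is.na(out$ref_pos_i) & !is.na(out$ref_pos_j)
  if (any(!out$mappable)) {
    message("evaluate_calls: ", sum(!out$mappable),
            " call(s) on reference-gapped columns are unmappable")
  }
  out$class <- structure_pair_class(structure, out$ref_pos_i, out$ref_pos_j)
  out$tp <- out$mappable & out$class %in% c("secondary", "tertiary")
  mapped <- out[out$mappable, , drop = FALSE]
  if (all(is.na(mapped$score))) {
    ranked_tp <- mapped$tp
  } else {
    ranked_tp <- mapped$tp[order(-mapped$score)]
  }
  topn <- data.frame(N = seq_along(ranked_tp),
                     precision = cumsum(ranked_tp) / seq_along(ranked_tp))
  summary <- list(
    n_calls = nrow(out), n_mappable = sum(out$mappable),
    true_positives = sum(mapped$tp), false_positives = sum(!mapped$tp),
    n_secondary = sum(mapped$class == "secondary"),
    n_tertiary = sum(mapped$class == "tertiary"),
    precision = if (nrow(mapped)) mean(mapped$tp) else NA_real_)
  structure(list(per_call = out, summary = summary, topn = topn),
            class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  s <- x$summary
  cat("calls:", s$n_calls, " mappable:", s$n_mappable,
      " TP:", s$true_positives, " FP:", s$false_positives,
      " precision:", format(s$precision, digits = 4), "\n")
  invisible(x)
}

#' Plot a precision-of-top-N curve
#'
#' @param evaluation A `call_evaluation`.
#' @param ... Passed to [graphics::plot()].
#' @return The evaluation, invisibly.
#' @export
plot_precision_topn <- function(evaluation, ...) {
  graphics::plot(evaluation$topn$N, evaluation$topn$precision, type = "s",
       xlab = "top N ranked pairs", ylab = "precision", ylim = c(0, 1), ...)
  invisible(evaluation)
}
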