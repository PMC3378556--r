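# Phylogenetic event counting: majority-parsimony ancestral pair states on
# a (possibly non-binary) tree, de-duplicated positive/negative event
# counts, and the CPE statistic.
#
# Pair types are coded 1..16 as (x - 1) * 4 + y with A=1 C=2 G=3 U=4, so
# integer order coincides with lexicographic order of the "X:Y" strings —
# which.max on a count vector therefore implements the documented
# lexicographic tie-break for free.

pair_type_label <- function(t) {
  paste0(NUC[(t - 1L) %/% 4L + 1L], ":", NUC[(t - 1L) %% 4L + 1L])
}

leaf_pair_types <- function(phylogeny, alignment, col_x, col_y) {
  row <- match(phylogeny$leaf_seq, alignment$ids)
  if (any(is.na(row) & !is.na(phylogeny$leaf_seq))) {
    bad <- phylogeny$leaf_seq[is.na(row) & !is.na(phylogeny$leaf_seq)]
    stop("leaf sequence(s) not in alignment: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x <- alignment$codes[, col_x][row]
  y <- alignment$codes[, col_y][row]
  t <- rep(NA_integer_, phylogeny$n_nodes)
  inf <- !is.na(x) & x <= 4L & y <= 4L
  t[inf] <- (x[inf] - 1L) * 4L + y[inf]
  t
}

#' Assign ancestral pair states by majority parsimony
#'
#' Maps the states of two alignment columns onto the phylogeny's leaves and
#' assigns every internal node the pair type occurring most frequently among
#' the leaves of its subtree (the "equality set" of a majority variant of
#' Fitch parsimony suited to non-binary trees). Ties break lexicographically
#' (`A < C < G < U` on the ordered pair string). Leaves carrying a gap or
#' ambiguity code at either column are excluded from the majority counts and
#' from event counting.
#'
#' @param phylogeny A `pec_phylogeny`.
#' @param alignment An `rna_alignment` containing every leaf sequence.
#' @param col_x,col_y Column indices.
#' @return An object of class `pair_state_assignment`: `node_type` (integer
#'   pair-type code per node, `NA` for uninformative subtrees),
#'   `node_label` (the `"X:Y"` string), `n_informative` leaves, and the
#'   column indices.
#' @export
assign_ancestral_pairs <- function(phylogeny, alignment, col_x, col_y) {
  t <- leaf_pair_types(phylogeny, alignment, col_x, col_y)
  n_inf <- sum(!is.na(t) & phylogeny$is_leaf)
  if (n_inf < 2L) {
    stop("fewer than 2 informative leaves at columns ", col_x, ",", col_y)
  }
  counts <- matrix(0L, nrow = 16L, ncol = phylogeny$n_nodes)
  leaf_idx <- which(phylogeny$is_leaf & !is.na(t))
  counts[cbind(t[leaf_idx], leaf_idx)] <- 1L
  node_type <- t
  for (v in phylogeny$postorder) {
    kids <- phylogeny$children[[v]]
    if (length(kids)) {
      cv <- .rowSums(counts[, kids, drop = FALSE], 16L, length(kids))
      counts[, v] <- cv
      if (any(cv > 0L)) node_type[v] <- which.max(cv)
    }
  }
  structure(
    list(node_type = node_type,
         node_label = ifelse(is.na(node_type), NA_character_,
                             pair_type_label(pmax(node_type, 1L))),
         n_informative = n_inf, col_x = col_x, col_y = col_y),
    class = "pair_state_assignment"
  )
}

#' Count phylogenetic events for a column pair
#'
#' At every internal node with assigned pair type `P`, the distinct child
#' pair types different from `P` are collected (leaf children contribute
#' their observed type, internal children their assigned type). Each
#' distinct type contributes exactly one event regardless of how many
#' children carry it — the de-duplication that guards against repeat
#' sampling of dense clades: positive when both symbols differ from `P`,
#' negative when exactly one does.
#'
#' @param assignment A `pair_state_assignment`.
#' @param phylogeny The `pec_phylogeny` the assignment was computed on.
#' @return An object of class `event_count`: `positive_events`,
#'   `negative_events`, `total_events`, `cpe` (`NA` when no events).
#' @export
count_events <- function(assignment, phylogeny) {
  nt <- assignment$node_type
  pos <- 0L
  neg <- 0L
  for (v in which(!phylogeny$is_leaf)) {
    p <- nt[v]
    if (is.na(p)) next
    kt <- nt[phylogeny$children[[v]]]
    kt <- unique(kt[!is.na(kt)])
    kt <- kt[kt != p]
    if (!length(kt)) next
    pa <- (p - 1L) %/% 4L
    pb <- (p - 1L) %% 4L
    d1 <- (kt - 1L) %/% 4L != pa
    d2 <- (kt - 1L) %% 4L != pb
    pos <- pos + sum(d1 & d2)
    neg <- neg + sum(xor(d1, d2))
  }
  event_count(pos, neg)
}

event_count <- function(positive, negative) {
  total <- positive + negative
  structure(
    list(positive_events = as.integer(positive),
         negative_events = as.integer(negative),
         total_events = as.integer(total),
         cpe = if (total > 0) positive / total else NA_real_),
    class = "event_count"
  )
}

#' @export
print.event_count <- function(x, ...) {
  cat("events: +", x$positive_events, " -", x$negative_events,
      " total ", x$total_events, "  CPE ",
      if (is.na(x$cpe)) "undefined" else format(x$cpe, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Covariation percentage of events
#'
#' `CPE = positive / (positive + negative)`; 1 means every observed change
#' was compensatory (both positions changed together).
#'
#' @param events An `event_count`.
#' @return CPE in `[0, 1]`, `NA` when no events were observed.
#' @export
cpe <- function(events) {
  events$cpe
}

#' Scan column pairs with the event-counting method
#'
#' Runs [assign_ancestral_pairs()] and [count_events()] for every candidate
#' pair. Pairs with fewer total events than `min_total_events` are retained
#' in the output but flagged `excluded` (the total-event threshold that
#' suppresses background noise); pairs with fewer than 2 informative leaves
#' are reported with `NA` scores and flagged.
#'
#' @param alignment An `rna_alignment`.
#' @param phylogeny A `pec_phylogeny`.
#' @param pairs Two-column matrix/data.frame of candidate column pairs
#'   (e.g. from [coarse_filter()]).
#' @param min_total_events Optional minimum total events (the study default
#'   is 10); `NULL` retains all scored pairs.
#' @return A data frame of class `pec_result` with columns `col_i`, `col_j`,
#'   `positive_events`, `negative_events`, `total_events`, `cpe`,
#'   `excluded`.
#' @export
pec_scan <- function(alignment, phylogeny, pairs, min_total_events = NULL) {
  leaf_ids <- phylogeny$leaf_seq[phylogeny$is_leaf]
  if (anyNA(match(leaf_ids, alignment$ids))) {
    stop("phylogeny leaves missing from alignment: ",
         paste(utils::head(setdiff(leaf_ids, alignment$ids), 5L),
               collapse = ", "))
  }
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  n <- nrow(pairs)
  pos <- neg <- integer(n)
  cpe_v <- numeric(n)
  skipped <- logical(n)
  for (r in seq_len(n)) {
    a <- tryCatch(
      assign_ancestral_pairs(phylogeny, alignment, pairs[r, 1L], pairs[r, 2L]),
      error = function(e) NULL)
    if (is.null(a)) {
      skipped[r] <- TRUE
      pos[r] <- neg[r] <- NA_integer_
      cpe_v[r] <- NA_real_
      next
    }
    ev <- count_events(a, phylogeny)
    pos[r] <- ev$positive_events
    neg[r] <- ev$negative_events
    cpe_v[r] <- ev$cpe
  }
  if (any(skipped)) {
    message("pec_scan: ", sum(skipped),
            " pair(s) skipped (fewer than 2 informative leaves)")
  }
  total <- pos + neg
  excluded <- skipped
  if (!is.null(min_total_events)) {
    excluded <- excluded | (!is.na(total) & total < min_total_events)
  }
  out <- data.frame(col_i = pairs[, 1L], col_j = pairs[, 2L],
                    positive_events = pos, negative_events = neg,
                    total_events = total, cpe = cpe_v, excluded = excluded)
  class(out) <- c("pec_result", "data.frame")
  out
}

#' Extract the CPE score matrix from a PEC scan
#'
#' Keeps scored, non-excluded pairs with a defined CPE.
#'
#' @param pec A `pec_result` from [pec_scan()].
#' @return A `score_matrix` of CPE values.
#' @export
cpe_scores <- function(pec) {
  keep <- !pec$excluded & !is.na(pec$cpe)
  score_matrix(data.frame(col_i = pec$col_i[keep], col_j = pec$col_j[keep],
                          score = pec$cpe[keep]), method = "CPE")
}
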