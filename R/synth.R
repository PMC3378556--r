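# Seeded generator of phylogenies and alignments with planted covariation
# structure: compensatory (jointly substituting) column pairs, helix blocks
# whose flanking pairs are invariant canonical, independently evolving
# unpaired columns, conserved columns, and static gap columns. Discrete
# per-edge Bernoulli substitutions keep the emitted truth comparable with
# event counts.

#' Specify a synthetic covariation data set
#'
#' The defaults describe the package's reference study conditions: a
#' 200-leaf random multifurcating tree, 120 columns, 20 planted
#' compensatory pairs of which 3 sit at the centre of 5-pair helices whose
#' flanking pairs are invariant canonical.
#'
#' @param n_leaves Number of leaf sequences.
#' @param tree_shape `"multifurcating"` (random, out-degree 2-4),
#'   `"balanced"`, or `"star"`.
#' @param n_columns Alignment columns.
#' @param n_planted_pairs Planted compensatory pairs (includes the helix
#'   centre pairs).
#' @param compensatory_rate Per-edge probability that a planted pair
#'   substitutes jointly to another canonical pair.
#' @param n_helices,helix_length Helix blocks; each centre pair is planted,
#'   the remaining pairs are invariant canonical.
#' @param unpaired_rate Per-edge substitution probability of an unpaired
#'   variable column.
#' @param conserved_fraction Fraction of columns that never change.
#' @param gap_fraction Fraction of columns that are all-gap.
#' @param gu_prob Probability that a compensatory substitution visits a
#'   wobble (G:U/U:G) state instead of a canonical one.
#' @param seed Integer seed; the simulation is byte-identical under a
#'   fixed seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_leaves = 200, tree_shape = c("multifurcating",
                                                      "balanced", "star"),
                       n_columns = 120, n_planted_pairs = 20,
                       compensatory_rate = 0.10, n_helices = 3,
                       helix_length = 5, unpaired_rate = 0.04,
                       conserved_fraction = 0.15, gap_fraction = 0.05,
                       gu_prob = 0, seed = 1) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_leaves >= 2, n_columns >= 2, n_planted_pairs >= 0,
            compensatory_rate >= 0, compensatory_rate <= 1,
            unpaired_rate >= 0, unpaired_rate <= 1,
            conserved_fraction >= 0, gap_fraction >= 0,
            gu_prob >= 0, gu_prob <= 1, n_helices >= 0, helix_length >= 1)
  if (n_helices > 0 && helix_length %% 2 == 0) {
    stop("helix_length must be odd so each helix has a centre pair")
  }
  if (n_helices > n_planted_pairs) {
    stop("each helix needs a planted centre pair: n_helices > n_planted_pairs")
  }
  paired_cols <- 2 * (n_helices * helix_length +
                        (n_planted_pairs - n_helices))
  fixed_cols <- paired_cols + round(conserved_fraction * n_columns) +
    round(gap_fraction * n_columns)
  if (fixed_cols > n_columns) {
    stop("infeasible spec: ", fixed_cols, " columns needed, ",
         n_columns, " available")
  }
  structure(
    list(n_leaves = n_leaves, tree_shape = tree_shape, n_columns = n_columns,
         n_planted_pairs = n_planted_pairs,
         compensatory_rate = compensatory_rate, n_helices = n_helices,
         helix_length = helix_length, unpaired_rate = unpaired_rate,
         conserved_fraction = conserved_fraction,
         gap_fraction = gap_fraction, gu_prob = gu_prob, seed = seed),
    class = "synth_spec"
  )
}

# random multifurcating topology by recursive partition of the leaf set
build_tree_children <- function(n_leaves, shape) {
  children <- list()
  new_node <- function() {
    children[[length(children) + 1L]] <<- integer(0)
    length(children)
  }
  grow <- function(leaves) {
    v <- new_node()
    n <- length(leaves)
    if (n == 1L) return(v)
    if (shape == "star" && n > 1L) {
      for (lf in leaves) {
        k <- new_node()
        children[[v]] <<- c(children[[v]], k)
      }
      return(v)
    }
    k <- if (shape == "balanced") 2L else sample(2:min(4L, n), 1L)
    grp <- sort(sample.int(k, n, replace = TRUE))
    while (length(unique(grp)) < k) grp <- sort(sample.int(k, n, replace = TRUE))
    if (shape == "balanced") grp <- rep(1:2, length.out = n)[order(seq_len(n))]
    for (g in unique(grp)) {
      sub <- leaves[grp == g]
      kid <- grow(sub)
      children[[v]] <<- c(children[[v]], kid)
    }
    v
  }
  root <- grow(seq_len(n_leaves))
  list(children = children, root = root)
}

#' Simulate an alignment, a phylogeny, and the truth table
#'
#' Evolves sequences from a uniformly drawn root state down the tree.
#' Planted pairs substitute jointly between canonical partners
#' (G:C, C:G, A:U, U:A, optionally visiting G:U/U:G); unpaired variable
#' columns substitute independently; conserved columns never change; gap
#' columns are `-` in every sequence; helix flanking pairs are invariant
#' canonical so the 85% helix-extension rule holds by construction.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_data`: `alignment` (`rna_alignment`),
#'   `phylogeny` (`pec_phylogeny`), `truth` (data frame of planted and
#'   flanking pairs with roles and helix ids), `column_roles` (per-column
#'   role vector), `spec`.
#' @export
synth_simulate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)

  # --- column layout ---------------------------------------------------
  n_col <- spec$n_columns
  role <- rep("unpaired", n_col)
  partner <- rep(NA_integer_, n_col)
  helix_id <- rep(NA_integer_, n_col)
  truth <- list()
  cursor <- 1L
  for (h in seq_len(spec$n_helices)) {
    L <- spec$helix_length
    i0 <- cursor
    j0 <- cursor + 2L * L + 3L  # 4-column loop between the strands
    for (s in seq_len(L)) {
      i <- i0 + s - 1L
      j <- j0 - s + 1L
      centre <- s == (L + 1L) %/% 2L
      role[c(i, j)] <- if (centre) "planted" else "helix_flank"
      partner[i] <- j
      partner[j] <- i
      helix_id[c(i, j)] <- h
      truth[[length(truth) + 1L]] <- data.frame(
        col_i = i, col_j = j,
        role = if (centre) "planted" else "helix_flank", helix = h)
    }
    # mark the 4 loop columns unpaired-variable; they stay in place
    cursor <- j0 + 2L
  }
  free <- setdiff(which(role == "unpaired"), which(!is.na(partner)))
  n_standalone <- spec$n_planted_pairs - spec$n_helices
  if (length(free) < 2L * n_standalone) stop("layout infeasible")
  pick <- sample(free, 2L * n_standalone)
  for (k in seq_len(n_standalone)) {
    i <- min(pick[c(2L * k - 1L, 2L * k)])
    j <- max(pick[c(2L * k - 1L, 2L * k)])
    role[c(i, j)] <- "planted"
    partner[i] <- j
    partner[j] <- i
    truth[[length(truth) + 1L]] <- data.frame(col_i = i, col_j = j,
                                              role = "planted",
                                              helix = NA_integer_)
  }
  free <- setdiff(which(role == "unpaired"), which(!is.na(partner)))
  n_cons <- round(spec$conserved_fraction * n_col)
  n_gap <- round(spec$gap_fraction * n_col)
  pick <- sample(free, min(length(free), n_cons + n_gap))
  role[pick[seq_len(min(n_cons, length(pick)))]] <- "conserved"
  if (length(pick) > n_cons) role[pick[(n_cons + 1L):length(pick)]] <- "gap"
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(col_i = integer(0), col_j = integer(0),
               role = character(0), helix = integer(0))
  truth <- truth[order(truth$col_i), , drop = FALSE]
  rownames(truth) <- NULL

  # --- tree ------------------------------------------------------------
  top <- build_tree_children(spec$n_leaves, spec$tree_shape)
  is_leaf <- lengths(top$children) == 0L
  leaf_nodes <- which(is_leaf)
  seq_ids <- sprintf("seq_%04d", seq_along(leaf_nodes))
  leaf_seq <- rep(NA_character_, length(top$children))
  leaf_seq[leaf_nodes] <- seq_ids
  phy <- phylogeny(top$children, labels = leaf_seq, leaf_seq = leaf_seq)

  # --- evolution -------------------------------------------------------
  canon <- matrix(c(3L, 2L, 2L, 3L, 1L, 4L, 4L, 1L), ncol = 2L,
                  byrow = TRUE)  # GC CG AU UA as (5', 3') codes
  wobble <- matrix(c(3L, 4L, 4L, 3L), ncol = 2L, byrow = TRUE)
  anchor <- which(!is.na(partner) & seq_len(n_col) < partner)
  root_state <- integer(n_col)
  for (j in which(role %in% c("unpaired", "conserved"))) {
    root_state[j] <- sample.int(4L, 1L)
  }
  for (i in anchor) {
    p <- canon[sample.int(4L, 1L), ]
    root_state[i] <- p[1L]
    root_state[partner[i]] <- p[2L]
  }
  root_state[role == "gap"] <- GAP_CODE

  planted_anchor <- anchor[role[anchor] == "planted"]
  unpaired_cols <- which(role == "unpaired")
  states <- matrix(0L, nrow = phy$n_nodes, ncol = n_col)
  states[phy$root, ] <- root_state
  # preorder = reverse postorder: parents before children
  for (v in rev(phy$postorder)) {
    if (v == phy$root) next
    s <- states[phy$parent[v], ]
    hit <- planted_anchor[stats::runif(length(planted_anchor)) <
                            spec$compensatory_rate]
    for (i in hit) {
      cur <- s[c(i, partner[i])]
      pool <- canon
      if (spec$gu_prob > 0 && stats::runif(1L) < spec$gu_prob) pool <- wobble
      pool <- pool[!(pool[, 1L] == cur[1L] & pool[, 2L] == cur[2L]), ,
                   drop = FALSE]
      nxt <- pool[sample.int(nrow(pool), 1L), ]
      s[i] <- nxt[1L]
      s[partner[i]] <- nxt[2L]
    }
    hit <- unpaired_cols[stats::runif(length(unpaired_cols)) <
                           spec$unpaired_rate]
    for (j in hit) {
      s[j] <- sample(setdiff(1:4, s[j]), 1L)
    }
    states[v, ] <- s
  }

  chars <- matrix(c(NUC, "-")[states[leaf_nodes, , drop = FALSE]],
                  nrow = length(leaf_nodes))
  rownames(chars) <- seq_ids
  aln <- rna_alignment(chars)
  structure(list(alignment = aln, phylogeny = phy, truth = truth,
                 column_roles = role, spec = spec),
            class = "synth_data")
}

#' Write a simulation to disk
#'
#' Writes the aligned FASTA, the Newick tree, and the truth TSV.
#'
#' @param sim A `synth_data` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  as_newick(sim$phylogeny, file.path(dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
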