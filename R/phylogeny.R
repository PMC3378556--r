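# Rooted, possibly multifurcating phylogeny with sequences attached to
# leaves. Kept as flat parent/children arrays so the event-counting engine
# can traverse it without recursion.

#' Construct a phylogeny
#'
#' Low-level constructor for the rooted (possibly multifurcating) phylogeny
#' used by the event-counting engine. Most users will prefer
#' [read_phylogeny()] or [as_pec_phylogeny()].
#'
#' @param children List with one integer vector per node giving its child
#'   node indices (empty vector for leaves). Exactly one node must have no
#'   parent; cycles are rejected.
#' @param labels Optional character vector of node labels.
#' @param leaf_seq Character vector, one element per node: the sequence
#'   identifier attached to a leaf, `NA` for internal nodes. Defaults to
#'   `labels` on leaves.
#' @return An object of class `pec_phylogeny` with elements `children`,
#'   `parent`, `labels`, `leaf_seq`, `is_leaf`, `root`, `postorder`,
#'   `n_nodes` and `n_leaves`.
#' @export
phylogeny <- function(children, labels = NULL, leaf_seq = NULL) {
  n <- length(children)
  children <- lapply(children, as.integer)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    for (k in children[[v]]) {
      if (!is.na(parent[k])) stop("node ", k, " has two parents")
      parent[k] <- v
    }
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) {
    stop("phylogeny must have exactly one root, found ", length(root))
  }
  is_leaf <- lengths(children) == 0L
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(leaf_seq)) {
    leaf_seq <- ifelse(is_leaf, labels, NA_character_)
  }
  po <- postorder_nodes(children, root)
  if (length(po) != n) stop("disconnected or cyclic phylogeny")
  structure(
    list(children = children, parent = parent, labels = as.character(labels),
         leaf_seq = as.character(leaf_seq), is_leaf = is_leaf, root = root,
         postorder = po, n_nodes = n, n_leaves = sum(is_leaf)),
    class = "pec_phylogeny"
  )
}

# Iterative post-order: children always precede their parent.
postorder_nodes <- function(children, root) {
  n <- length(children)
  order <- integer(n)
  stack <- integer(n)
  stack[1L] <- root
  top <- 1L
  pos <- n
  seen <- logical(n)
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    if (seen[v]) stop("cycle detected in phylogeny")
    seen[v] <- TRUE
    order[pos] <- v
    pos <- pos - 1L
    kids <- children[[v]]
    if (length(kids)) {
      stack[(top + 1L):(top + length(kids))] <- kids
      top <- top + length(kids)
    }
  }
  if (pos != 0L) order <- order[(pos + 1L):n]
  order
}

#' @export
print.pec_phylogeny <- function(x, ...) {
  cat("Phylogeny:", x$n_leaves, "leaves,", x$n_nodes, "nodes",
      "(max out-degree", max(lengths(x$children)), ")\n")
  invisible(x)
}

ape_to_phylogeny <- function(tree) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  children <- vector("list", n)
  for (v in seq_len(n)) children[[v]] <- integer(0)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1L]
    children[[p]] <- c(children[[p]], tree$edge[r, 2L])
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep(NA_character_, tree$Nnode))
  phylogeny(children, labels = labels)
}

#' Read a phylogeny from Newick or an NCBI taxonomy dump
#'
#' Reads the tree, attaches alignment sequences to its nodes through an
#' optional sequence-to-node mapping, prunes nodes that carry no sequences,
#' and collapses single-child chains (splicing a unary node cannot change
#' event counts, because no majority-parsimony state change can occur across
#' a unary edge).
#'
#' Several sequences may map to the same node (common when a public taxonomy
#' has one taxon for many alignment records); each becomes its own leaf
#' under that node.
#'
#' @param path Newick file, or `nodes.dmp` of an NCBI taxdump.
#' @param format `"newick"` or `"taxdump"`.
#' @param mapping Optional two-column mapping from sequence id to tree node
#'   label (a data.frame, or the path of a headerless two-column TSV). When
#'   `NULL`, leaf labels are taken to be sequence ids.
#' @param alignment Optional `rna_alignment`; when given, alignment
#'   sequences absent from the mapping/tree are reported and dropped with a
#'   warning rather than an error.
#' @return A `pec_phylogeny` whose leaves carry sequence ids in `leaf_seq`.
#' @export
read_phylogeny <- function(path, format = c("newick", "taxdump"),
                           mapping = NULL, alignment = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  base <- if (format == "newick") {
    tree <- ape::read.tree(path)
    if (is.null(tree)) stop("could not parse Newick file: ", path)
    ape_to_phylogeny(tree)
  } else {
    taxdump_to_phylogeny(path, mapping)
  }
  attach_sequences(base, mapping = mapping, alignment = alignment)
}

#' Convert an ape tree to the package's phylogeny
#'
#' @param tree An [ape::read.tree()] `phylo` object (multifurcations allowed).
#' @inheritParams read_phylogeny
#' @return A `pec_phylogeny`.
#' @export
as_pec_phylogeny <- function(tree, mapping = NULL, alignment = NULL) {
  attach_sequences(ape_to_phylogeny(tree), mapping = mapping,
                   alignment = alignment)
}

read_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- utils::read.table(mapping, sep = "\t", header = FALSE,
                                 colClasses = "character",
                                 col.names = c("sequence_id", "node"))
  }
  mapping <- as.data.frame(mapping)
  names(mapping)[1:2] <- c("sequence_id", "node")
  mapping$sequence_id <- as.character(mapping$sequence_id)
  mapping$node <- as.character(mapping$node)
  mapping
}

# Attach sequences to nodes by label, prune sequence-free leaves, collapse
# unary chains, renumber compactly.
attach_sequences <- function(phy, mapping = NULL, alignment = NULL) {
  if (is.null(mapping)) {
    labs <- phy$labels[phy$is_leaf]
    mapping <- data.frame(sequence_id = labs, node = labs,
                          stringsAsFactors = FALSE)
  } else {
    mapping <- read_mapping(mapping)
  }
  if (!is.null(alignment)) {
    missing_seq <- setdiff(alignment$ids, mapping$sequence_id)
    mapping <- mapping[mapping$sequence_id %in% alignment$ids, , drop = FALSE]
    if (length(missing_seq)) {
      warning(length(missing_seq), " alignment sequence(s) absent from the ",
              "tree mapping were dropped: ",
              paste(utils::head(missing_seq, 5L), collapse = ", "),
              if (length(missing_seq) > 5L) ", ...")
    }
  }
  bad <- setdiff(mapping$node, phy$labels)
  if (length(bad)) {
    stop("mapping refers to node label(s) not in the tree: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }

  # grow arrays: one new leaf per mapped sequence under its node
  children <- phy$children
  labels <- phy$labels
  leaf_seq <- rep(NA_character_, phy$n_nodes)
  node_of <- match(mapping$node, phy$labels)
  for (k in seq_len(nrow(mapping))) {
    new <- length(children) + 1L
    children[[new]] <- integer(0)
    labels[new] <- mapping$sequence_id[k]
    leaf_seq[new] <- mapping$sequence_id[k]
    children[[node_of[k]]] <- c(children[[node_of[k]]], new)
  }
  n <- length(children)

  # prune: iteratively drop nodes that carry no sequence and no kept child
  length(leaf_seq) <- n
  keep <- rep(TRUE, n)
  repeat {
    n_eff <- vapply(seq_len(n), function(v) sum(keep[children[[v]]]),
                    integer(1))
    drop <- which(keep & is.na(leaf_seq) & n_eff == 0L)
    if (!length(drop)) break
    keep[drop] <- FALSE
  }
  if (sum(keep & !is.na(leaf_seq)) < 2L) {
    stop("fewer than 2 sequences could be attached to the tree")
  }

  # rebuild with pruning + unary collapse
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) for (k in children[[v]]) parent[k] <- v
  root <- which(is.na(parent) & keep)
  root <- root[vapply(root, function(v) {
    length(children[[v]][keep[children[[v]]]]) > 0L || !is.na(leaf_seq[v])
  }, logical(1))]
  if (length(root) != 1L) stop("pruned tree has no unique root")

  effective_children <- function(v) children[[v]][keep[children[[v]]]]
  # collapse: walk down through unary internal nodes
  resolve <- function(v) {
    repeat {
      kids <- effective_children(v)
      if (length(kids) == 1L && is.na(leaf_seq[v])) v <- kids else return(v)
    }
  }
  new_children <- list()
  new_labels <- character(0)
  new_leaf_seq <- character(0)
  index_of <- integer(n)
  build <- function(v) {
    v <- resolve(v)
    id <- length(new_children) + 1L
    new_children[[id]] <<- integer(0)
    new_labels[id] <<- labels[v]
    new_leaf_seq[id] <<- leaf_seq[v]
    index_of[v] <<- id
    kids <- effective_children(v)
    for (k in kids) {
      cid <- build(k)
      new_children[[id]] <<- c(new_children[[id]], cid)
    }
    id
  }
  old_exp <- options(expressions = 500000L)
  on.exit(options(old_exp))
  build(root)
  phylogeny(new_children, labels = new_labels, leaf_seq = new_leaf_seq)
}

# nodes.dmp: tax_id | parent_id | rank | ... ; root has parent == itself.
taxdump_to_phylogeny <- function(path, mapping) {
  if (is.null(mapping)) {
    stop("taxdump input requires a sequence-to-taxon mapping")
  }
  mapping <- read_mapping(mapping)
  lines <- readLines(path)
  fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  tax_id <- vapply(fields, `[`, character(1), 1L)
  parent_id <- vapply(fields, `[`, character(1), 2L)
  parent_of <- stats::setNames(parent_id, tax_id)

  wanted <- unique(mapping$node)
  missing_tax <- setdiff(wanted, tax_id)
  if (length(missing_tax)) {
    stop("mapping refers to taxon id(s) not in nodes.dmp: ",
         paste(utils::head(missing_tax, 10L), collapse = ", "))
  }
  induced <- character(0)
  for (t in wanted) {
    chain <- character(0)
    v <- t
    repeat {
      chain <- c(chain, v)
      p <- parent_of[[v]]
      if (is.null(p) || p == v) break
      v <- p
      if (v %in% induced) { chain <- c(chain, v); break }
    }
    induced <- union(induced, chain)
  }
  idx <- stats::setNames(seq_along(induced), induced)
  children <- vector("list", length(induced))
  for (v in seq_along(induced)) children[[v]] <- integer(0)
  for (t in induced) {
    p <- parent_of[[t]]
    if (!is.null(p) && p != t && p %in% induced) {
      children[[idx[[p]]]] <- c(children[[idx[[p]]]], idx[[t]])
    }
  }
  phylogeny(children, labels = induced)
}

#' Write a phylogeny as Newick
#'
#' @param phy A `pec_phylogeny`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(phy, path = NULL) {
  rec <- function(v) {
    kids <- phy$children[[v]]
    if (!length(kids)) {
      lab <- if (!is.na(phy$leaf_seq[v])) phy$leaf_seq[v] else phy$labels[v]
      return(lab)
    }
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
  }
  old_exp <- options(expressions = 500000L)
  on.exit(options(old_exp))
  s <- paste0(rec(phy$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
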