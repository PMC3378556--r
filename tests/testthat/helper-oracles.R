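# Independent brute-force oracles used to verify the package's
# implementations. These are deliberately naive re-derivations from the
# stated rules and share no code with the package.

# --- event counting on a nested-list tree -------------------------------
# tree: either an integer (leaf index) or an unnamed list of subtrees.
# states: character vector of "X:Y" pair strings per leaf index (NA = leaf
# excluded for gap/ambiguity).
oracle_majority <- function(types) {
  tt <- table(types)
  sort(names(tt)[tt == max(tt)])[1L]
}

oracle_pec <- function(tree, states) {
  leaf_types <- function(nd) {
    if (!is.list(nd)) return(states[nd])
    unlist(lapply(nd, leaf_types))
  }
  assigned <- function(nd) {
    if (!is.list(nd)) return(states[nd])
    lt <- leaf_types(nd)
    lt <- lt[!is.na(lt)]
    if (!length(lt)) return(NA_character_)
    oracle_majority(lt)
  }
  pos <- 0L
  neg <- 0L
  walk <- function(nd) {
    if (!is.list(nd)) return(invisible(NULL))
    p <- assigned(nd)
    if (!is.na(p)) {
      kt <- vapply(nd, assigned, character(1))
      kt <- unique(kt[!is.na(kt)])
      kt <- setdiff(kt, p)
      for (k in kt) {
        d1 <- substr(k, 1L, 1L) != substr(p, 1L, 1L)
        d2 <- substr(k, 3L, 3L) != substr(p, 3L, 3L)
        if (d1 && d2) pos <<- pos + 1L else if (d1 || d2) neg <<- neg + 1L
      }
    }
    lapply(nd, walk)
    invisible(NULL)
  }
  walk(tree)
  list(positive = pos, negative = neg)
}

# --- enumeration of rooted multifurcating topologies --------------------
set_partitions <- function(xs) {
  if (length(xs) == 1L) return(list(list(xs)))
  rest <- set_partitions(xs[-1L])
  out <- list()
  for (p in rest) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], xs[1L])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(xs[1L]))
  }
  out
}

all_topologies <- function(leaves) {
  if (length(leaves) == 1L) return(list(leaves[1L]))
  out <- list()
  for (p in set_partitions(leaves)) {
    if (length(p) < 2L) next
    subs <- lapply(p, all_topologies)
    idx <- do.call(expand.grid, lapply(subs, seq_along))
    for (r in seq_len(nrow(idx))) {
      out[[length(out) + 1L]] <-
        lapply(seq_along(subs), function(b) subs[[b]][[idx[r, b]]])
    }
  }
  out
}

# --- bridges between nested trees and package objects -------------------
nested_to_phylogeny <- function(tree) {
  children <- list()
  leaf_seq <- character(0)
  add <- function(nd) {
    id <- length(children) + 1L
    children[[id]] <<- integer(0)
    leaf_seq[id] <<- NA_character_
    if (!is.list(nd)) {
      leaf_seq[id] <<- paste0("s", nd)
    } else {
      for (k in nd) {
        kid <- add(k)
        children[[id]] <<- c(children[[id]], kid)
      }
    }
    id
  }
  add(tree)
  rnacov::phylogeny(children, leaf_seq = leaf_seq)
}

phylogeny_to_nested <- function(phy) {
  rec <- function(v) {
    kids <- phy$children[[v]]
    if (!length(kids)) return(match(phy$leaf_seq[v],
                                    phy$leaf_seq[phy$is_leaf]))
    lapply(kids, rec)
  }
  rec(phy$root)
}

# alignment whose two columns carry the given pair states; "X:Y" or a raw
# 2-character row ("-N" etc) per leaf
pair_alignment <- function(states) {
  rows <- vapply(states, function(s) {
    if (is.na(s)) "--" else gsub(":", "", s, fixed = TRUE)
  }, character(1))
  rnacov::rna_alignment(stats::setNames(rows, paste0("s", seq_along(rows))))
}

run_pec <- function(tree, states) {
  phy <- nested_to_phylogeny(tree)
  aln <- pair_alignment(states)
  a <- rnacov::assign_ancestral_pairs(phy, aln, 1L, 2L)
  rnacov::count_events(a, phy)
}

# --- APC / OMES / purity oracles ----------------------------------------
oracle_apc_mip <- function(df) {
  cols <- sort(unique(c(df$col_i, df$col_j)))
  mean_col <- vapply(cols, function(cc) {
    mean(df$score[df$col_i == cc | df$col_j == cc])
  }, numeric(1))
  names(mean_col) <- cols
  overall <- mean(df$score)
  vapply(seq_len(nrow(df)), function(r) {
    df$score[r] - mean_col[as.character(df$col_i[r])] *
      mean_col[as.character(df$col_j[r])] / overall
  }, numeric(1))
}

oracle_omes <- function(cnt) {
  nt <- sum(cnt)
  s <- 0
  for (a in 1:4) {
    for (b in 1:4) {
      ne <- sum(cnt[a, ]) * sum(cnt[, b]) / nt
      s <- s + (cnt[a, b] - ne)^2
    }
  }
  s / nt
}

oracle_purity <- function(freqs, gu_plus = FALSE) {
  ord <- order(-freqs, names(freqs))
  types <- names(freqs)[ord]
  fr <- freqs[ord]
  wob <- c("G:U", "U:G")
  can <- c("A:U", "U:A", "G:C", "C:G")
  acc <- character(0)
  total <- 0
  for (k in seq_along(types)) {
    if (fr[k] <= 0) next
    t5 <- substr(types[k], 1L, 1L)
    t3 <- substr(types[k], 3L, 3L)
    ok <- TRUE
    for (a in acc) {
      exempt <- gu_plus &&
        ((types[k] %in% wob && a %in% c(can, wob)) ||
           (a %in% wob && types[k] %in% c(can, wob)))
      if (exempt) next
      if (t5 == substr(a, 1L, 1L) || t3 == substr(a, 3L, 3L)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      acc <- c(acc, types[k])
      total <- total + fr[k]
    }
  }
  unname(total)
}

random_nested_tree <- function(n) {
  build <- function(leaves) {
    if (length(leaves) == 1L) return(leaves)
    k <- sample(2:min(3L, length(leaves)), 1L)
    grp <- sample(rep(seq_len(k), length.out = length(leaves)))
    lapply(seq_len(k), function(g) build(leaves[grp == g]))
  }
  build(seq_len(n))
}

# add replicate leaves as siblings of `leaf`
graft_replicates <- function(tree, leaf, new_ids) {
  if (!is.list(tree)) return(tree)
  out <- lapply(tree, graft_replicates, leaf = leaf, new_ids = new_ids)
  direct <- vapply(tree, function(x) !is.list(x) && x == leaf, logical(1))
  if (any(direct)) out <- c(out, as.list(new_ids))
  out
}

# TRUE when any internal node's majority pair type is tied
has_majority_tie <- function(tree, states) {
  tie <- FALSE
  leaf_types <- function(nd) {
    if (!is.list(nd)) return(states[nd])
    unlist(lapply(nd, leaf_types))
  }
  walk <- function(nd) {
    if (!is.list(nd)) return(invisible(NULL))
    lt <- leaf_types(nd)
    lt <- lt[!is.na(lt)]
    if (length(lt)) {
      tt <- table(lt)
      if (sum(tt == max(tt)) > 1L) tie <<- TRUE
    }
    lapply(nd, walk)
    invisible(NULL)
  }
  walk(tree)
  tie
}

# TRUE when the leaf's type is the majority at every ancestor on its root
# path, so replicating it cannot flip any majority
leaf_replication_safe <- function(tree, states, leaf) {
  ok <- TRUE
  leaf_types <- function(nd) {
    if (!is.list(nd)) return(states[nd])
    unlist(lapply(nd, leaf_types))
  }
  rec <- function(nd) {
    if (!is.list(nd)) return(nd == leaf)
    contains <- any(vapply(nd, rec, logical(1)))
    if (contains) {
      lt <- leaf_types(nd)
      lt <- lt[!is.na(lt)]
      if (oracle_majority(lt) != states[leaf]) ok <<- FALSE
    }
    contains
  }
  rec(tree)
  ok
}

shannon_bits_oracle <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# random 4x4 pair-type count matrix
random_pair_counts <- function(max_types = 6L, max_count = 30L) {
  cnt <- matrix(0L, 4L, 4L, dimnames = list(c("A", "C", "G", "U"),
                                            c("A", "C", "G", "U")))
  k <- sample(1:max_types, 1L)
  cells <- sample(16L, k)
  cnt[cells] <- sample.int(max_count, k, replace = TRUE)
  cnt
}

freqs_from_counts <- function(cnt) {
  nucs <- c("A", "C", "G", "U")
  types <- as.vector(outer(nucs, nucs, function(a, b) paste0(a, ":", b)))
  f <- as.vector(cnt) / sum(cnt)
  stats::setNames(f, types)[f > 0]
}
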