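# Reference secondary/tertiary structure input: BPSEQ and CT files,
# tertiary-pair TSVs, and hydrogen-bond-edge base centers from a PDB file.

#' Default Watson-Crick-edge atoms used for base centers
#'
#' Atom names whose coordinates are averaged per residue to give the base
#' "hydrogen-bond center" used in distance calculations. Exposed so users
#' can swap in their own atom sets.
#'
#' @return Named list of atom-name vectors for residues A, C, G, U.
#' @export
wc_edge_atoms <- function() {
  list(A = c("N1", "C2", "N6"),
       G = c("N1", "N2", "O6"),
       C = c("N3", "O2", "N4"),
       U = c("N3", "O2", "O4"))
}

#' Read a BPSEQ file
#'
#' Line format: `position base partner` (partner 0 when unpaired).
#'
#' @param path BPSEQ file path.
#' @return List with `sequence` (character vector of bases) and `pairs`
#'   (data frame `pos_i < pos_j`).
#' @export
read_bpseq <- function(path) {
  tab <- utils::read.table(path, col.names = c("pos", "base", "partner"),
                           colClasses = c("integer", "character", "integer"))
  seq <- normalize_rna(tab$base[order(tab$pos)])
  partner <- integer(max(tab$pos))
  partner[tab$pos] <- tab$partner
  check_partner_consistency(partner)
  idx <- which(partner > 0 & seq_along(partner) < partner)
  list(sequence = seq,
       pairs = data.frame(pos_i = idx, pos_j = partner[idx]))
}

#' Read a CT file
#'
#' Connectivity-table format: a header line, then
#' `index base prev next partner ref_index` per residue.
#'
#' @param path CT file path.
#' @return As [read_bpseq()].
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]][1L]))
  if (is.na(n)) stop("CT header does not start with a residue count: ", path)
  body <- utils::read.table(text = lines[2:(n + 1L)],
                            colClasses = c("integer", "character", "integer",
                                           "integer", "integer", "integer"))
  names(body) <- c("pos", "base", "prev", "nxt", "partner", "ref")
  seq <- normalize_rna(body$base[order(body$pos)])
  partner <- integer(n)
  partner[body$pos] <- body$partner
  check_partner_consistency(partner)
  idx <- which(partner > 0 & seq_along(partner) < partner)
  list(sequence = seq,
       pairs = data.frame(pos_i = idx, pos_j = partner[idx]))
}

check_partner_consistency <- function(partner) {
  for (i in seq_along(partner)) {
    j <- partner[i]
    if (j > 0) {
      if (j == i) stop("position ", i, " paired to itself")
      if (j > length(partner) || partner[j] != i) {
        stop("inconsistent pairing: position ", i, " -> ", j,
             " but ", j, " -> ", if (j > length(partner)) "out of range"
             else partner[j])
      }
    }
  }
  invisible(TRUE)
}

#' Read a reference structure
#'
#' Secondary-structure pairs from a BPSEQ or CT file, optional tertiary
#' pairs from a two-column TSV, and optional per-position base centers
#' computed from a PDB file. All positions are 1-based ungapped
#' reference-sequence coordinates.
#'
#' @param path BPSEQ or CT file (format guessed from the extension, or set
#'   `format`).
#' @param reference_sequence_id Identifier of the reference sequence in the
#'   alignment this structure belongs to.
#' @param format `"bpseq"`, `"ct"`, or `"auto"`.
#' @param tertiary_tsv Optional headerless TSV of tertiary pair positions
#'   (two integer columns); rows are tagged class `"tertiary"`.
#' @param pdb Optional PDB file for base centers.
#' @param chain PDB chain identifier (default: first chain with nucleic
#'   residues).
#' @param edge_atoms Atom sets averaged per residue; see [wc_edge_atoms()].
#' @return An object of class `reference_structure`: `reference_sequence_id`,
#'   `sequence`, `length`, `pairs` (data frame `pos_i`, `pos_j`, `class`),
#'   `base_centers` (L x 3 matrix of Angstrom coordinates or `NULL`).
#' @export
read_reference_structure <- function(path, reference_sequence_id,
                                     format = c("auto", "bpseq", "ct"),
                                     tertiary_tsv = NULL, pdb = NULL,
                                     chain = NULL,
                                     edge_atoms = wc_edge_atoms()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ct$", path, ignore.case = TRUE)) "ct" else "bpseq"
  }
  sec <- if (format == "ct") read_ct(path) else read_bpseq(path)
  pairs <- sec$pairs
  pairs$class <- rep("secondary", nrow(pairs))
  if (!is.null(tertiary_tsv)) {
    tert <- utils::read.table(tertiary_tsv,
                              col.names = c("pos_i", "pos_j"))
    tert <- data.frame(pos_i = pmin(tert$pos_i, tert$pos_j),
                       pos_j = pmax(tert$pos_i, tert$pos_j),
                       class = "tertiary")
    key <- paste(pairs$pos_i, pairs$pos_j)
    tert <- tert[!(paste(tert$pos_i, tert$pos_j) %in% key), , drop = FALSE]
    pairs <- rbind(pairs, tert)
  }
  L <- length(sec$sequence)
  if (any(pairs$pos_j > L) || any(pairs$pos_i < 1L)) {
    stop("structure pair positions outside sequence length ", L)
  }
  centers <- if (!is.null(pdb)) {
    base_centers_from_pdb(pdb, chain = chain, sequence = sec$sequence,
                          edge_atoms = edge_atoms)
  } else NULL
  structure(
    list(reference_sequence_id = reference_sequence_id,
         sequence = sec$sequence, length = L,
         pairs = pairs[order(pairs$pos_i, pairs$pos_j), , drop = FALSE],
         base_centers = centers),
    class = "reference_structure"
  )
}

# Per-residue WC-edge atom centers from a PDB file; residue numbers are the
# reference positions. A sequence cross-check guards against chain offsets.
base_centers_from_pdb <- function(pdb, chain = NULL, sequence = NULL,
                                  edge_atoms = wc_edge_atoms()) {
  model <- bio3d::read.pdb(pdb, verbose = FALSE)
  atoms <- model$atom
  nuc_resid <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
  atoms <- atoms[atoms$resid %in% nuc_resid, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no nucleic-acid residues in PDB: ", pdb)
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no nucleic residues in chain ", chain)
  resno <- sort(unique(atoms$resno))
  if (!is.null(sequence)) {
    in_range <- resno[resno >= 1 & resno <= length(sequence)]
    pdb_base <- vapply(in_range, function(r) {
      sub("^D", "", atoms$resid[atoms$resno == r][1L])
    }, character(1))
    pdb_base[pdb_base == "T"] <- "U"
    mism <- in_range[pdb_base != sequence[in_range]]
    if (length(mism) > 0.05 * length(in_range)) {
      stop("PDB chain ", chain, " disagrees with the reference sequence at ",
           length(mism), "/", length(in_range), " positions (first offsets: ",
           paste(utils::head(mism, 5L), collapse = ", "), ")")
    }
  }
  L <- if (!is.null(sequence)) length(sequence) else max(resno)
  centers <- matrix(NA_real_, nrow = L, ncol = 3L,
                    dimnames = list(NULL, c("x", "y", "z")))
  for (r in resno[resno >= 1 & resno <= L]) {
    res <- atoms[atoms$resno == r, , drop = FALSE]
    base <- sub("^D", "", res$resid[1L])
    if (base == "T") base <- "U"
    want <- edge_atoms[[base]]
    sel <- res[res$elety %in% want, , drop = FALSE]
    if (nrow(sel) == 0L) next
    centers[r, ] <- c(mean(sel$x), mean(sel$y), mean(sel$z))
  }
  centers
}

#' Distance between two base hydrogen-bond centers
#'
#' Euclidean distance (Angstrom) between the per-base centers of the
#' Watson-Crick-edge atoms at two reference positions.
#'
#' @param structure A `reference_structure` with `base_centers`.
#' @param pos_a,pos_b Reference positions (1-based).
#' @return Distance in Angstrom, or `NA` with a warning when either
#'   position lacks coordinates.
#' @export
base_center_distance <- function(structure, pos_a, pos_b) {
  if (is.null(structure$base_centers)) {
    stop("reference structure has no base centers (no PDB was supplied)")
  }
  a <- structure$base_centers[pos_a, ]
  b <- structure$base_centers[pos_b, ]
  if (anyNA(a) || anyNA(b)) {
    warning("missing coordinates for position ",
            if (anyNA(a)) pos_a else pos_b)
    return(NA_real_)
  }
  sqrt(sum((a - b)^2))
}

# Look up the annotation class of a reference-position pair.
structure_pair_class <- function(structure, pos_i, pos_j) {
  if (is.null(structure)) return(rep("unknown", length(pos_i)))
  key <- paste(pmin(pos_i, pos_j), pmax(pos_i, pos_j))
  ref_key <- paste(structure$pairs$pos_i, structure$pairs$pos_j)
  cls <- structure$pairs$class[match(key, ref_key)]
  out <- ifelse(is.na(cls), "none", cls)
  out[is.na(pos_i) | is.na(pos_j)] <- "unknown"
  out
}
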