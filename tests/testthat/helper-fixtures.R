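# Small fixture builders shared across test files.

aln_from_rows <- function(...) {
  rows <- c(...)
  if (is.null(names(rows))) names(rows) <- paste0("s", seq_along(rows))
  rna_alignment(rows)
}

star_phylogeny <- function(ids) {
  n <- length(ids)
  children <- c(list(seq_len(n) + 1L), rep(list(integer(0)), n))
  phylogeny(children, leaf_seq = c(NA_character_, ids))
}

write_fasta_tmp <- function(rows) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  out <- character(2L * length(rows))
  out[c(TRUE, FALSE)] <- paste0(">", names(rows))
  out[c(FALSE, TRUE)] <- rows
  writeLines(out, path)
  path
}

# minimal single-chain PDB text for two bases with chosen WC-edge centers;
# synthetic fixture, not a real structure
write_synthetic_pdb <- function(centers, bases = c("G", "C")) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  atoms_for <- list(G = c("N1", "N2", "O6"), C = c("N3", "O2", "N4"),
                    A = c("N1", "C2", "N6"), U = c("N3", "O2", "O4"))
  lines <- character(0)
  serial <- 0L
  for (r in seq_along(bases)) {
    for (at in atoms_for[[bases[r]]]) {
      serial <- serial + 1L
      xyz <- centers[r, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, at, bases[r], r, xyz[1], xyz[2], xyz[3],
        substr(at, 1L, 1L)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
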