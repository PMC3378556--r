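bpseq_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bpseq",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("BPSEQ and CT parsing recover the pair list", {
  bp <- read_bpseq(bpseq_tmp(c("1 G 8", "2 C 7", "3 A 0", "4 A 0",
                               "5 U 0", "6 G 0", "7 G 2", "8 C 1")))
  expect_equal(bp$pairs, data.frame(pos_i = c(1L, 2L), pos_j = c(8L, 7L)))
  expect_equal(bp$sequence, c("G", "C", "A", "A", "U", "G", "G", "C"))

  # inconsistent partner annotation
  expect_error(read_bpseq(bpseq_tmp(c("1 G 3", "2 C 0", "3 C 2"))),
               "inconsistent")
  expect_error(read_bpseq(bpseq_tmp("1 G 1")), "itself")

  ct <- c("8 synthetic", "1 G 0 2 8 1", "2 C 1 3 7 2", "3 A 2 4 0 3",
          "4 A 3 5 0 4", "5 U 4 6 0 5", "6 G 5 7 0 6", "7 G 6 8 2 7",
          "8 C 7 0 1 8")
  path <- withr::local_tempfile(fileext = ".ct")
  writeLines(ct, path)
  got <- read_ct(path)
  expect_equal(got$pairs, data.frame(pos_i = c(1L, 2L), pos_j = c(8L, 7L)))
})

test_that("reference structures combine secondary and tertiary pairs", {
  bp <- bpseq_tmp(c("1 G 8", "2 C 7", "3 A 0", "4 A 0", "5 U 0", "6 G 0",
                    "7 G 2", "8 C 1"))
  tert <- withr::local_tempfile(fileext = ".tsv")
  writeLines("3\t6", tert)
  rs <- read_reference_structure(bp, "ref", tertiary_tsv = tert)
  expect_equal(rs$length, 8L)
  expect_equal(nrow(rs$pairs), 3L)
  expect_equal(rs$pairs$class[rs$pairs$pos_i == 3], "tertiary")
  expect_equal(sort(rs$pairs$class), c("secondary", "secondary", "tertiary"))
  expect_null(rs$base_centers)
  expect_error(base_center_distance(rs, 1, 8), "no base centers")
})

test_that("base centers from a synthetic PDB give hand-computed distances", {
  centers <- rbind(c(0, 0, 0), c(3, 4, 0))
  pdb <- write_synthetic_pdb(centers, bases = c("G", "C"))
  bp <- bpseq_tmp(c("1 G 2", "2 C 1"))
  rs <- read_reference_structure(bp, "ref", pdb = pdb)
  expect_equal(unname(rs$base_centers[1, ]), c(0, 0, 0))
  expect_equal(unname(rs$base_centers[2, ]), c(3, 4, 0))
  expect_equal(base_center_distance(rs, 1, 2), 5)
  expect_equal(base_center_distance(rs, 1, 1), 0)
})

test_that("PDB/sequence mismatches are reported with offsets", {
  centers <- rbind(c(0, 0, 0), c(3, 4, 0))
  pdb <- write_synthetic_pdb(centers, bases = c("G", "C"))
  bp <- bpseq_tmp(c("1 A 2", "2 U 1"))  # disagrees with the PDB bases
  expect_error(read_reference_structure(bp, "ref", pdb = pdb),
               "disagrees")
})

test_that("helix extension walks while the canonical fraction holds", {
  # 10 sequences, 12 columns; plant a helix at (4,9),(5,8) and degrade (3,10)
  n <- 10
  rows <- character(n)
  for (s in seq_len(n)) {
    r <- rep("A", 12)
    r[5] <- "G"; r[8] <- "C"            # 100% G:C
    r[4] <- "A"; r[9] <- "U"            # 100% A:U
    r[3] <- "G"; r[10] <- if (s <= 8) "C" else "A"  # 80% canonical
    rows[s] <- paste(r, collapse = "")
  }
  aln <- aln_from_rows(rows)
  he <- helix_extend(aln, data.frame(col_i = 5, col_j = 8),
                     canonical_fraction = 0.85)
  expect_equal(he$extended[c("col_i", "col_j")],
               data.frame(col_i = 4L, col_j = 9L))
  expect_equal(he$extended$canonical_fraction, 1)
  # (3,10) at 80% < 85% stops the outward walk
  expect_false(any(he$extended$col_i == 3))
  # lowering the bar admits it
  he2 <- helix_extend(aln, data.frame(col_i = 5, col_j = 8),
                      canonical_fraction = 0.8)
  expect_true(any(he2$extended$col_i == 3 & he2$extended$col_j == 10))
  # every extended pair re-checks against the threshold
  for (r in seq_len(nrow(he2$extended))) {
    f <- canonical_pair_fraction(aln, he2$extended$col_i[r],
                                 he2$extended$col_j[r])
    expect_gte(f$fraction, 0.8)
  }
})

test_that("helix extension respects alignment edges and inward collision", {
  aln <- aln_from_rows("GAC", "GAC", "GGC", "GCC")
  # nucleation at (1,3): outward leaves the alignment, inward would pair a
  # column with itself -> no extension either way
  he <- helix_extend(aln, data.frame(col_i = 1, col_j = 3))
  expect_equal(nrow(he$extended), 0)
})

test_that("canonical fraction counts wobble pairs and skips gapped rows", {
  aln <- aln_from_rows("GU", "GC", "G-", "NC")
  f <- canonical_pair_fraction(aln, 1, 2)
  expect_equal(f$n, 2L)  # gapped and ambiguous rows out of the denominator
  expect_equal(f$fraction, 1)  # G:U and G:C both count
})

test_that("purity reproduces the worked examples", {
  mk <- function(...) {
    cnt <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
    for (e in list(...)) cnt[e[[1]], e[[2]]] <- e[[3]]
    cnt
  }
  # a full compensatory set is 100% pure at any frequencies
  p <- purity(mk(list("A", "U", 40), list("G", "C", 30), list("U", "A", 20),
                 list("C", "G", 10)))
  expect_equal(p$purity, 1)
  expect_equal(p$gu_plus_purity, 1)
  # one nucleotide partnered with everything: only the top type survives
  p2 <- purity(mk(list("A", "A", 40), list("A", "G", 30), list("A", "C", 20),
                  list("A", "U", 10)))
  expect_equal(p2$purity, 0.4)
  # wobble blocked classically, credited by GU-plus
  p3 <- purity(mk(list("A", "U", 50), list("G", "C", 30), list("G", "U", 20)))
  expect_equal(p3$purity, 0.8)
  expect_equal(p3$gu_plus_purity, 1)
  # non-canonical 1:1 sets are pure too
  p4 <- purity(mk(list("A", "G", 60), list("G", "A", 40)))
  expect_equal(p4$purity, 1)
  expect_error(purity(mk()), "empty")
})

test_that("purity matches the oracle walk; GU-plus never scores lower", {
  set.seed(47)
  for (k in 1:100) {
    cnt <- random_pair_counts()
    if (sum(cnt) == 0) next
    p <- purity(cnt)
    fr <- freqs_from_counts(cnt)
    expect_equal(p$purity, oracle_purity(fr, gu_plus = FALSE),
                 tolerance = 1e-12)
    expect_equal(p$gu_plus_purity, oracle_purity(fr, gu_plus = TRUE),
                 tolerance = 1e-12)
    expect_gte(p$gu_plus_purity, p$purity)
    expect_gt(p$purity, 0)
    expect_lte(p$gu_plus_purity, 1)
  }
})

test_that("neighbor effects apply all three thresholds and the call mask", {
  pec <- data.frame(
    col_i = c(1, 1, 4, 7),
    col_j = c(2, 3, 5, 8),
    positive_events = c(6, 5, 2, 6),
    negative_events = c(6, 6, 8, 6),
    total_events = c(12, 11, 10, 12),
    cpe = c(0.5, 0.45, 0.2, 0.5),
    excluded = FALSE)
  class(pec) <- c("pec_result", "data.frame")
  # ratios: col1 sees 0.5 and 0.45 -> 0.9; cols 4,5,7,8 single-partner
  ne <- neighbor_effects(pec, ratio_min = 0.85, cpe_min = 0.25,
                         events_min = 10)
  expect_equal(nrow(ne), 2)
  expect_setequal(paste(ne$col_i, ne$col_j), c("1 2", "1 3"))
  expect_equal(ne$nbest_ratio, c(0.9, 0.9))
  expect_equal(ne$h_bonded_class, c("unknown", "unknown"))
  # (4,5) fails the CPE floor even with a qualifying ratio profile
  expect_false(any(ne$col_i == 4))
  # masking the called pair removes it from candidacy
  ne2 <- neighbor_effects(pec, called_pairs = data.frame(col_i = 1, col_j = 2),
                          ratio_min = 0.85, cpe_min = 0.25, events_min = 10)
  expect_equal(paste(ne2$col_i, ne2$col_j), "1 3")
  # an event floor above the observed totals empties the list
  ne3 <- neighbor_effects(pec, ratio_min = 0.85, cpe_min = 0.25,
                          events_min = 13)
  expect_equal(nrow(ne3), 0)
})

test_that("neighbor effects pick up distances and structure classes", {
  centers <- rbind(c(0, 0, 0), c(3, 4, 0))
  pdb <- write_synthetic_pdb(centers, bases = c("G", "C"))
  bp <- bpseq_tmp(c("1 G 2", "2 C 1"))
  rs <- read_reference_structure(bp, "ref", pdb = pdb)
  aln <- aln_from_rows(ref = "GC", o = "GC")
  pm <- build_position_map(aln, "ref")
  pec <- data.frame(col_i = 1, col_j = 2, positive_events = 6,
                    negative_events = 6, total_events = 12, cpe = 0.5,
                    excluded = FALSE)
  class(pec) <- c("pec_result", "data.frame")
  # single pair: per-column ratio 0 -> not a neighbor effect
  ne0 <- neighbor_effects(pec, structure = rs, position_map = pm)
  expect_equal(nrow(ne0), 0)
  ne <- neighbor_effects(pec, structure = rs, position_map = pm,
                         ratio_min = 0)
  expect_equal(ne$distance, 5)
  expect_equal(ne$h_bonded_class, "secondary")
})

test_that("evaluation splits TP/FP, drops unmappable calls, builds the curve", {
  bp <- bpseq_tmp(c("1 G 4", "2 C 3", "3 G 2", "4 C 1"))
  rs <- read_reference_structure(bp, "ref")
  aln <- aln_from_rows(ref = "G-CGC", o = "GACGC")
  pm <- build_position_map(aln, "ref")
  calls <- data.frame(col_i = c(1, 3, 1, 2),
                      col_j = c(5, 4, 3, 4),
                      score = c(0.9, 0.8, 0.7, 0.6))
  ev <- suppressMessages(evaluate_calls(calls, pm, rs))
  # (1,5)->(1,4) TP; (3,4)->(2,3) TP; (1,3)->(1,2) FP; (2,4) unmappable
  expect_equal(ev$summary$n_mappable, 3)
  expect_equal(ev$summary$true_positives, 2)
  expect_equal(ev$summary$false_positives, 1)
  expect_equal(ev$summary$precision, 2 / 3)
  expect_equal(ev$topn$precision, c(1, 1, 2 / 3))
  # at N = all calls the curve equals overall precision
  expect_equal(ev$topn$precision[nrow(ev$topn)], ev$summary$precision)
})
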