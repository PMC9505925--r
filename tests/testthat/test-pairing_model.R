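test_that("pair taxonomy is symmetric and classifies WC, wobble and U-U", {
  expect_identical(pair_type("A", "U"), "WC")
  expect_identical(pair_type("G", "C"), "WC")
  expect_identical(pair_type("G", "U"), "WOBBLE")
  expect_identical(pair_type("U", "U"), "NONCANONICAL_UU")
  expect_identical(pair_type("A", "G"), "NONE")
  bases <- c("A", "C", "G", "U")
  for (x in bases) for (y in bases) {
    expect_identical(pair_type(x, y), pair_type(y, x))
  }
  expect_warning(t <- pair_type("N", "A"), "NONE")
  expect_identical(t, "NONE")
})

test_that("motif registry ships the U1, U2 and U6 recognition sequences", {
  reg <- snrna_motifs()
  expect_identical(reg[["U1_5p"]], "ACUUACCU")
  expect_identical(reg[["U2_BP"]], "GUAGUA")
  expect_identical(reg[["U6_ACAGAGA"]], "ACAGAGA")
})

test_that("duplex alignment finds the full complement and rejects tiny regions", {
  aln <- duplex_align("AAAA", "UUUU")
  expect_identical(aln$score, 8)           # 4 WC pairs at weight 2
  expect_identical(nrow(aln$pairs), 4L)
  expect_true(all(aln$pairs$type == "WC"))
  # antiparallel monotonicity: region positions up, motif positions down
  expect_true(all(diff(aln$pairs$region_pos) > 0))
  expect_true(all(diff(aln$pairs$motif_pos) < 0))
  expect_error(duplex_align("A", "UUUU"), "shorter")
})

test_that("duplex alignment equals the brute-force oracle over random cases", {
  set.seed(314)
  w <- c(WC = 2, WOBBLE = 1, NONCANONICAL_UU = 1)
  motifs <- c(unname(snrna_motifs()), replicate(10, random_rna(sample(2:8, 1))))
  for (i in 1:40) {
    region <- random_rna(sample(2:8, 1))
    motif <- sample(motifs, 1)
    got <- duplex_align(region, motif, weights = w)
    want <- oracle_best_duplex(region, motif, w)
    expect_identical(got$score, want$score)
    expect_identical(got$offset, as.integer(want$offset))
    # and with a bulge at every possible region position
    for (b in seq_len(nchar(region))) {
      if (nchar(region) < 3) next
      got_b <- duplex_align(region, motif, weights = w, bulge_at = b)
      want_b <- oracle_best_duplex(region, motif, w, bulge_at = b)
      expect_identical(got_b$score, want_b$score)
      expect_false(b %in% got_b$pairs$region_pos)
    }
  }
})

test_that("score never decreases when a pairable flank position is added", {
  set.seed(271)
  for (i in 1:20) {
    region <- random_rna(sample(3:7, 1))
    motif <- random_rna(sample(3:7, 1))
    base <- duplex_align(region, motif)$score
    extended <- duplex_align(paste0(region, "A"), motif)$score
    expect_gte(extended, base)
  }
})

test_that("branch helix bulges the branchpoint adenosine out of the pairing", {
  seq <- "GUAAUUUUUAUAUAG"
  bp <- call_branchpoint(seq)
  bh <- branch_helix(seq, bp)
  expect_identical(bh$bulge, 10L)
  expect_false(10L %in% bh$pairs$region_pos)
  expect_identical(bh$region, substr(seq, 6, 12))  # b-4 .. b+2
  # oracle over the bulged branch window (region coords shifted by 5)
  want <- oracle_best_duplex(substr(seq, 6, 12), "GUAGUA",
                             c(WC = 2, WOBBLE = 1, NONCANONICAL_UU = 1),
                             bulge_at = 5)
  expect_identical(bh$score, want$score)
  expect_gt(bh$score, 0)

  # all-C branch region: only G-C pairs can score, and GUAGUA has two Gs
  allc <- branch_helix("GGGGGCCCCACCCGG", 10L)
  expect_identical(allc$score, 4)
  expect_true(all(allc$pairs$type[allc$pairs$type != "NONE"] == "WC"))
  expect_true(all(allc$pairs$motif_base[allc$pairs$type == "WC"] == "G"))

  expect_error(branch_helix(seq, call_branchpoint("GUUUUUUUUUUUUAG")),
               "no-call")
  expect_error(branch_helix(seq, 40L), "outside")
})

test_that("the network report contains one scored duplex per snRNA motif", {
  introns <- data.frame(
    gene_id = "g", seq_id = "s", start = 1L, end = 15L, strand = "+",
    length = 15L, sequence = "GUAAUUUUUAUAUAG", flank5 = "CAAUUG",
    flank3 = "AAA", flank5_truncated = FALSE, flank3_truncated = FALSE,
    has_n = FALSE, stringsAsFactors = FALSE)
  net <- network_report(introns)
  expect_named(net$alignments, c("U1_5p", "U6_ACAGAGA", "U2_BP"))
  expect_identical(net$bp, 10L)
  expect_identical(net$ss5_region, "UUGGUAAUU")   # 3 exonic + 6 intronic nt
  expect_identical(net$alignments$U2_BP$bulge, 10L)
  # determinism: identical input, byte-identical rendering
  expect_identical(format(network_report(introns)),
                   format(network_report(introns)))
  txt <- format(net)
  expect_true(any(grepl("•|bulged", txt)))
  # the U-U glyph convention
  uu <- duplex_align("UU", "UU")
  expect_identical(unname(tinyintron:::pair_glyph("NONCANONICAL_UU")), "•")
  expect_identical(uu$pairs$type, rep("NONCANONICAL_UU", 2))
})
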