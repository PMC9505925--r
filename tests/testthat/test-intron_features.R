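test_that("length shares reproduce the cohort arithmetic with half-up rounding", {
  # the 8806-intron cohort: 8173 15-nt (92.81%), 633 16-nt (7.19%)
  d <- classify_lengths(c("15" = 8173L, "16" = 633L))
  expect_identical(d$share, c(92.81, 7.19))
  expect_identical(classify_lengths(c("15" = 3L, "16" = 1L))$share,
                   c(75.00, 25.00))
  expect_identical(classify_lengths(rep(15L, 1))$share, 100.00)
  expect_error(classify_lengths(c("15" = 0L)), "no introns")
  # shares sum to 100 within rounding slack
  set.seed(7)
  lens <- sample(14:17, 500, replace = TRUE)
  expect_lt(abs(sum(classify_lengths(lens)$share) - 100), 0.05)
})

test_that("terminal dinucleotides and the GU...AG fraction are tallied", {
  expect_equal(terminal_dinucleotides("GUAAUUUUUAUAUAG")$gu_ag_fraction, 1.0)
  expect_equal(terminal_dinucleotides("AUAAUUUUUAUAUAC")$gu_ag_fraction, 0.0)
  mixed <- c("GUAAAAG", "GUCCCAG", "AUAAAAG", "GUAAAAC")
  expect_equal(terminal_dinucleotides(mixed)$gu_ag_fraction, 0.5)
  expect_warning(res <- terminal_dinucleotides(c("GUA", "GUAAAG")),
                 "shorter")
  expect_identical(res$n_used, 1L)
})

test_that("position frequency matrix and information content follow the entropy formula", {
  introns <- data.frame(
    gene_id = letters[1:4], seq_id = "s", start = 1L, end = 8L,
    strand = "+", length = 8L,
    sequence = c("GUAAAAAG", "GUAAAAAG", "GUUAAAAG", "GUGAAAAG"),
    flank5 = "CCC", flank3 = "GGG",
    flank5_truncated = FALSE, flank3_truncated = FALSE, has_n = FALSE,
    stringsAsFactors = FALSE)
  pfm <- build_pfm(introns, 8L, flank = 2L)
  expect_identical(pfm$positions,
                   c("-2", "-1", as.character(1:8), "+1", "+2"))
  expect_true(all(abs(colSums(pfm$freq) - 1) < 1e-9))
  # invariant columns carry 2 bits
  expect_equal(unname(pfm$info[["1"]]), 2)
  # column 3 is A,A,U,G: freqs .5/.25/.25, H = 1.5, info = 0.5
  expect_equal(unname(pfm$freq["A", "3"]), 0.5)
  expect_equal(unname(pfm$info[["3"]]), 0.5)
  # a 50/50 column carries 1 bit
  two <- introns[1:2, ]
  two$sequence <- c("GUAAAAAG", "GUUAAAAG")
  expect_equal(unname(build_pfm(two, 8L, flank = 0L)$info[["3"]]), 1)
  expect_error(build_pfm(introns[0, ], 8L), "no introns")
})

test_that("branchpoint calling prefers the canonical L-5 adenosine", {
  rep15 <- call_branchpoint("GUAAUUUUUAUAUAG")
  expect_identical(rep15$position, 10L)
  expect_true(rep15$canonical)

  # canonical A present among earlier As: canonical wins
  expect_identical(call_branchpoint("GUAAUUUUAAUUUAG")$position, 10L)
  # no A anywhere in the window: no-call
  nc <- call_branchpoint("GUUUUUUUUUUUUAG")
  expect_true(is.na(nc$position))
  # fallback: nearest A, ties broken toward 3'
  expect_identical(call_branchpoint("GUUUUUUUAUUUUAG")$position, 9L)
  expect_identical(call_branchpoint("GUUUUUUUAUAUUAG")$position, 11L)
  # 16-nt intron: canonical position 11
  expect_identical(call_branchpoint("GUAAUUUUUUAUAUAG")$position, 11L)
  expect_error(call_branchpoint("GUAAAG"), "shorter")
})

test_that("branchpoint position distribution uses the full-cohort denominator", {
  # 8005 calls at 10 and 442 at 11 out of 8806 introns
  d <- bp_position_distribution(c(rep(10L, 3), rep(11L, 1), NA), total = 8806L)
  expect_identical(attr(d, "no_call"), 1L)
  d2 <- bp_position_distribution(rep(10L, 8005), total = 8806L)
  expect_identical(d2$percent, 90.90)
  d3 <- bp_position_distribution(rep(11L, 442), total = 8806L)
  expect_identical(d3$percent, 5.02)
  expect_identical(bp_position_distribution(10L, total = 1L)$percent, 100.00)
  expect_error(bp_position_distribution(integer(0), total = 0L), "positive")
  expect_error(bp_position_distribution(rep(10L, 5), total = 3L), "smaller")
})

test_that("composition reports per-intron fractions and both AU summaries", {
  comp <- composition("GUAAUUUUUAUAUAG")
  expect_equal(comp$au_pooled_percent, tinyintron::round_half_up(1300 / 15))
  expect_equal(comp$per_intron$au_percent, 100 * 13 / 15)
  expect_equal(composition("GGGG")$au_pooled_percent, 0)
  expect_equal(composition("AUAU")$au_pooled_percent, 100)
  expect_true(all(abs(rowSums(
    composition(c("GUAAUG", "AUAUAU"))$per_intron[, c("A", "C", "G", "U")])
    - 1) < 1e-12))
  expect_error(composition("NNNN"), "no N-free")
})

test_that("unique-intron tally ranks by count with the class denominator", {
  # 127 occurrences over the 8173-strong 15-nt class is 1.55%
  expect_identical(tinyintron::percent_share(127, 8173), 1.55)
  seqs <- c(rep("GUAAUUUUUAUAUAG", 3), rep("GUAAAUUUUAUAUAG", 2),
            "GUAAUUUUUUAUAUAG")  # two 15-nt variants + one 16-nt
  tab <- tally_unique_introns(seqs, "class")
  expect_identical(tab$sequence[1], "GUAAUUUUUAUAUAG")
  expect_identical(tab$percent[1], 60.00)           # 3 of 5 in the class
  expect_identical(tab$percent[tab$length == 16L], 100.00)
  coh <- tally_unique_introns(seqs, "cohort")
  expect_identical(coh$percent[1], 50.00)           # 3 of 6 overall
  # ties broken lexicographically
  tie <- tally_unique_introns(c("GUAAAG", "GUCCAG"))
  expect_identical(tie$sequence, c("GUAAAG", "GUCCAG"))
  one <- tally_unique_introns(rep("GUAAAG", 4))
  expect_identical(one$percent, 100.00)
})

test_that("lariat geometry conserves loop + tail = L", {
  g15 <- lariat_geometry("GUAAUUUUUAUAUAG", call_branchpoint("GUAAUUUUUAUAUAG"))
  expect_identical(g15$loop_length, 10L)
  expect_identical(g15$tail_length, 5L)
  expect_identical(g15$branch_nt, "A")

  g16 <- lariat_geometry(16L, 11L)
  expect_identical(g16$loop_length, 11L)
  expect_identical(g16$tail_length, 5L)

  degen <- lariat_geometry(15L, 15L)
  expect_true(degen$degenerate)
  expect_identical(degen$tail_length, 0L)

  expect_error(lariat_geometry("GUUUUUUUUUUUUAG",
                               call_branchpoint("GUUUUUUUUUUUUAG")),
               "no-call")
  # conservation across random calls
  set.seed(11)
  for (i in 1:20) {
    L <- sample(12:20, 1)
    b <- sample(seq_len(L), 1)
    g <- lariat_geometry(L, b)
    expect_identical(g$loop_length + g$tail_length, L)
  }
})
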