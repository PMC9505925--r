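test_that("FASTA reading normalizes case, joins wrapped lines, rejects bad input", {
  fa <- write_fixture_fasta(c(">s1", "ac", "gt"))
  expect_identical(read_genome(fa), c(s1 = "ACGT"))

  dup <- write_fixture_fasta(c(">s1", "ACGT", ">s1", "TTTT"))
  expect_error(read_genome(dup), "duplicate")

  empty <- write_fixture_fasta(character(0))
  expect_error(read_genome(empty))

  ambig <- write_fixture_fasta(c(">s1", "ACGRT"))
  expect_warning(g <- read_genome(ambig), "ambiguity")
  expect_identical(unname(g), "ACGNT")
})

test_that("explicit-introns and exon-gaps modes agree on the fixture annotation", {
  fx <- fixture_files(explicit = TRUE)
  ann_e <- read_annotation(fx$gff, "explicit-introns")
  ann_g <- read_annotation(fx$gff, "exon-gaps")

  expect_s3_class(ann_e, "intron_annotation")
  expect_identical(nrow(ann_e$genes), 3L)
  expect_identical(ann_e$introns[ann_e$introns$gene_id == "gA", c("start", "end")],
                   data.frame(start = 51L, end = 65L))
  # intronless gene retained with zero count
  expect_identical(ann_e$genes$n_introns[ann_e$genes$gene_id == "gC"], 0L)
  # gap arithmetic (exons 11..50 and 66..110 -> intron 51..65) agrees with
  # the explicit intron rows for both strands
  expect_identical(ann_g$introns[order(ann_g$introns$gene_id), ],
                   ann_e$introns[order(ann_e$introns$gene_id), ])
})

test_that("orphan features are skipped with a warning; no gene rows is an error", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tt\tgene\t1\t100\t.\t+\t.\tID=gA",
               "s1\tt\tintron\t41\t55\t.\t+\t.\tParent=ghost"), gff)
  expect_warning(ann <- read_annotation(gff, "explicit-introns"),
                 "resolvable")
  expect_identical(nrow(ann$introns), 0L)

  nogene <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tt\texon\t1\t40\t.\t+\t.\tParent=ghost"), nogene)
  expect_error(suppressWarnings(read_annotation(nogene)), "gene")
})

test_that("extraction is strand-aware, maps T to U, and truncates flanks at ends", {
  fx <- fixture_files()
  genome <- read_genome(fx$fasta)
  ann <- read_annotation(fx$gff, "explicit-introns")
  introns <- extract_introns(genome, ann, flank = 4L)

  plus <- introns[introns$gene_id == "gA", ]
  minus <- introns[introns$gene_id == "gB", ]
  expect_identical(plus$sequence, "GUAAGUUUUUAUAAG")
  # minus strand: genomic slice CTATATAAAAATTAC reverse-complemented
  expect_identical(minus$sequence, "GUAAUUUUUAUAUAG")
  expect_identical(minus$strand, "-")
  # genomic coordinates stay plus-strand
  expect_identical(minus[, c("start", "end")],
                   data.frame(start = 41L, end = 55L, row.names = 2L))
  # flanks: transcript orientation, exon side adjacent to the splice sites
  expect_identical(plus$flank5, tinyintron:::dna_to_rna(substr(genome[["s1"]], 47, 50)))
  expect_identical(minus$flank5,
                   tinyintron:::dna_to_rna(tinyintron:::revcomp_dna(substr(genome[["s2"]], 56, 59))))

  # truncation at sequence start
  short <- extract_introns(c(s = "GTAAGTTTTTATAAGCCCC"),
                           data.frame(gene_id = "g", seq_id = "s",
                                      start = 1L, end = 15L, strand = "+"),
                           flank = 3L)
  expect_identical(short$flank5, "")
  expect_true(short$flank5_truncated)
  expect_false(short$flank3_truncated)

  expect_error(
    extract_introns(genome, data.frame(gene_id = "gX", seq_id = "s1",
                                       start = 110L, end = 130L,
                                       strand = "+")),
    "gX")
})

test_that("strand property: mirrored extraction from the reverse-complemented genome matches", {
  set.seed(42)
  chrom <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
  rc <- function(x) tinyintron:::revcomp_dna(x)
  for (iv in list(c(20L, 34L), c(100L, 115L))) {
    fwd <- extract_introns(c(s = chrom),
                           data.frame(gene_id = "g", seq_id = "s",
                                      start = iv[1], end = iv[2],
                                      strand = "+"), flank = 0L)
    mirrored_start <- 200L - iv[2] + 1L
    mirrored_end <- 200L - iv[1] + 1L
    rev <- extract_introns(c(s = rc(chrom)),
                           data.frame(gene_id = "g", seq_id = "s",
                                      start = mirrored_start,
                                      end = mirrored_end, strand = "-"),
                           flank = 0L)
    expect_identical(fwd$sequence, rev$sequence)
  }
})

test_that("written intron FASTA round-trips and empty cohorts give valid outputs", {
  fx <- fixture_files()
  introns <- extract_introns(read_genome(fx$fasta),
                             read_annotation(fx$gff), flank = 4L)
  dir <- file.path(tempfile(), "out")
  paths <- write_intron_outputs(introns, dir)
  reread <- Biostrings::readRNAStringSet(paths[["fasta"]])
  expect_identical(unname(as.character(reread)), introns$sequence)
  expect_match(names(reread)[1], "^gA\\|s1\\|51-65\\|\\+$")
  tsv <- read.delim(paths[["tsv"]])
  expect_identical(nrow(tsv), nrow(introns))

  empty <- introns[0, ]
  paths0 <- write_intron_outputs(empty, file.path(tempfile(), "empty"))
  expect_identical(nrow(read.delim(paths0[["tsv"]])), 0L)
})
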