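# tiny hand-built genome/annotation fixtures, written to tempfiles in code

write_fixture_fasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# one plus-strand and one minus-strand gene, each with one 15-nt intron.
# s1: gene gA at 11..110 (+), intron 51..65 = GTAAGTTTTTATAAG
# s2: gene gB at 6..105 (-), intron 41..55 whose plus-strand slice
#     CTATATAAAAATTAC reverse-complements to GTAATTTTTATATAG (the
#     representative intron, RNA GUAAUUUUUAUAUAG)
fixture_genome_lines <- function() {
  base_a <- paste(rep("ACGTACGTAC", 12), collapse = "")  # 120 nt
  s1 <- paste0(substr(base_a, 1, 50), "GTAAGTTTTTATAAG",
               substr(base_a, 66, 120))
  s2 <- paste0(substr(base_a, 1, 40), "CTATATAAAAATTAC",
               substr(base_a, 56, 120))
  c(">s1 first scaffold", s1, ">s2", s2)
}

fixture_gff_lines <- function(explicit = TRUE) {
  rows <- c(
    "##gff-version 3",
    "s1\ttest\tgene\t11\t110\t.\t+\t.\tID=gA",
    "s1\ttest\tmRNA\t11\t110\t.\t+\t.\tID=gA.t1;Parent=gA",
    "s1\ttest\texon\t11\t50\t.\t+\t.\tParent=gA.t1",
    "s1\ttest\texon\t66\t110\t.\t+\t.\tParent=gA.t1",
    "s2\ttest\tgene\t6\t105\t.\t-\t.\tID=gB",
    "s2\ttest\tmRNA\t6\t105\t.\t-\t.\tID=gB.t1;Parent=gB",
    "s2\ttest\texon\t6\t40\t.\t-\t.\tParent=gB.t1",
    "s2\ttest\texon\t56\t105\t.\t-\t.\tParent=gB.t1",
    "s2\ttest\tgene\t110\t118\t.\t+\t.\tID=gC")
  if (explicit) {
    rows <- c(rows,
              "s1\ttest\tintron\t51\t65\t.\t+\t.\tParent=gA.t1",
              "s2\ttest\tintron\t41\t55\t.\t-\t.\tParent=gB.t1")
  }
  rows
}

fixture_files <- function(explicit = TRUE) {
  fa <- write_fixture_fasta(fixture_genome_lines())
  gff <- tempfile(fileext = ".gff3")
  writeLines(fixture_gff_lines(explicit), gff)
  list(fasta = fa, gff = gff)
}

# independent brute-force oracle for antiparallel duplex alignment: naive
# nested loops, no shared code with duplex_align()
oracle_pair_score <- function(x, y, w) {
  if ((x == "A" && y == "U") || (x == "U" && y == "A") ||
      (x == "G" && y == "C") || (x == "C" && y == "G")) return(w[["WC"]])
  if ((x == "G" && y == "U") || (x == "U" && y == "G")) return(w[["WOBBLE"]])
  if (x == "U" && y == "U") return(w[["NONCANONICAL_UU"]])
  0
}

oracle_best_duplex <- function(region, motif, w = c(WC = 2, WOBBLE = 1,
                                                    NONCANONICAL_UU = 1),
                               bulge_at = NULL) {
  rc <- strsplit(region, "")[[1]]
  pos <- seq_along(rc)
  if (!is.null(bulge_at)) {
    rc <- rc[-bulge_at]
    pos <- pos[-bulge_at]
  }
  mc <- strsplit(motif, "")[[1]]
  best <- -1
  best_d <- NA
  for (d in seq(1 - length(mc), length(rc) - 1)) {
    sc <- 0
    for (i in seq_along(rc)) {
      j <- i - d                      # index into reversed motif
      if (j >= 1 && j <= length(mc)) {
        sc <- sc + oracle_pair_score(rc[i], rev(mc)[j], w)
      }
    }
    if (sc > best) { best <- sc; best_d <- d }
  }
  list(score = best, offset = best_d)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
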