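#' Read a genome FASTA into a named vector of uppercase DNA strings
#'
#' Sequences are normalized to uppercase and the alphabet is restricted to
#' A/C/G/T/N; IUPAC ambiguity codes other than N are folded to N with a
#' warning.  Sequence ids are the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a (multi-)FASTA file.
#' @return named character vector, one uppercase DNA string per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in FASTA: ", path)
  has_ambig <- grepl("[^ACGTN]", seqs)
  if (any(has_ambig)) {
    warning(sum(has_ambig), " sequence(s) contain IUPAC ambiguity codes; ",
            "folded to N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  seqs
}

#' Read gene models and intron intervals from a GFF3 annotation
#'
#' Two ways of obtaining intron intervals are supported.  In
#' `"explicit-introns"` mode, features of type `intron` are attached to their
#' gene via the `Parent` attribute chain (intron -> mRNA -> gene, or intron ->
#' gene directly).  In `"exon-gaps"` mode, introns are inferred as the gaps
#' between consecutive exons of the same gene.  Genes with no introns are
#' retained with an empty interval set.  Intron (or exon) features whose
#' parent cannot be resolved to a gene are skipped with a warning; a feature
#' with start > end is a hard error.
#'
#' @param path path to a GFF3 file.
#' @param mode `"explicit-introns"` (default) or `"exon-gaps"`.
#' @return an object of class `intron_annotation`: a list with
#'   * `genes`: data.frame (`gene_id`, `seq_id`, `start`, `end`, `strand`,
#'     `gene_length`, `n_introns`),
#'   * `introns`: data.frame (`gene_id`, `start`, `end`) of 1-based inclusive
#'     genomic intervals, sorted by gene and genomic start.
#' @export
read_annotation <- function(path, mode = c("explicit-introns", "exon-gaps")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  gene_idx <- which(type == "gene")
  if (length(gene_idx) == 0L) stop("no gene features in GFF3: ", path)
  gene_ids <- ids[gene_idx]
  if (anyNA(gene_ids)) stop("gene feature without ID attribute in: ", path)

  # resolve any feature's Parent chain up to a gene id (bounded depth)
  parent_of <- stats::setNames(parents, ids)
  resolve_gene <- function(parent) {
    for (i in 1:5) {
      if (is.na(parent)) return(NA_character_)
      if (parent %in% gene_ids) return(parent)
      parent <- if (parent %in% names(parent_of)) parent_of[[parent]] else NA_character_
    }
    NA_character_
  }

  take <- if (mode == "explicit-introns") "intron" else "exon"
  feat_idx <- which(type == take)
  feat_gene <- vapply(parents[feat_idx], resolve_gene, character(1))
  bad <- is.na(feat_gene)
  if (any(bad)) {
    warning(sum(bad), " ", take,
            " feature(s) without resolvable gene parent; skipped")
    feat_idx <- feat_idx[!bad]
    feat_gene <- feat_gene[!bad]
  }

  genes <- data.frame(
    gene_id = gene_ids,
    seq_id = as.character(GenomicRanges::seqnames(gr))[gene_idx],
    start = GenomicRanges::start(gr)[gene_idx],
    end = GenomicRanges::end(gr)[gene_idx],
    strand = as.character(GenomicRanges::strand(gr))[gene_idx],
    stringsAsFactors = FALSE
  )
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("gene feature with missing/unstranded strand in: ", path)
  }
  genes$gene_length <- genes$end - genes$start + 1L

  feats <- data.frame(
    gene_id = feat_gene,
    start = GenomicRanges::start(gr)[feat_idx],
    end = GenomicRanges::end(gr)[feat_idx],
    stringsAsFactors = FALSE
  )
  feats <- feats[order(match(feats$gene_id, genes$gene_id), feats$start), ,
                 drop = FALSE]

  introns <- if (mode == "explicit-introns") {
    feats
  } else {
    # gaps between consecutive exons of the same gene (isoform-merged)
    out <- lapply(split(feats, feats$gene_id), function(d) {
      red <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      gaps <- IRanges::gaps(red,
                            start = min(IRanges::start(red)),
                            end = max(IRanges::end(red)))
      data.frame(gene_id = rep(d$gene_id[1], length(gaps)),
                 start = IRanges::start(gaps), end = IRanges::end(gaps),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    if (is.null(out)) {
      data.frame(gene_id = character(), start = integer(), end = integer())
    } else {
      out[order(match(out$gene_id, genes$gene_id), out$start), , drop = FALSE]
    }
  }
  rownames(introns) <- NULL

  # containment checks against the owning gene
  g <- genes[match(introns$gene_id, genes$gene_id), ]
  if (nrow(introns) && any(introns$start < g$start | introns$end > g$end)) {
    stop("intron interval outside its gene span in: ", path)
  }
  genes$n_introns <- as.integer(table(factor(introns$gene_id,
                                             levels = genes$gene_id)))
  structure(list(genes = genes, introns = introns, mode = mode),
            class = "intron_annotation")
}

#' @export
print.intron_annotation <- function(x, ...) {
  cat("intron_annotation:", nrow(x$genes), "genes,", nrow(x$introns),
      "intron intervals (mode:", x$mode, ")\n")
  invisible(x)
}

#' Extract intron sequences (with exonic flanks) from a genome
#'
#' Sequences are reported 5'->3' in transcript orientation: minus-strand
#' intervals are reverse-complemented, and DNA T is mapped to RNA U.  Genomic
#' `start`/`end` always remain plus-strand coordinates.  Flanks are the
#' adjacent genomic context in transcript orientation (so `flank5` ends at the
#' exon|intron boundary); flanks are truncated at sequence ends and flagged.
#'
#' @param genome named character vector from [read_genome()].
#' @param annotation an `intron_annotation` from [read_annotation()], or a
#'   data.frame with columns `gene_id`, `seq_id`, `start`, `end`, `strand`.
#' @param flank width in nt of exonic context on each side (default 8).
#' @return data.frame with one row per intron: `gene_id`, `seq_id`, `start`,
#'   `end`, `strand`, `length`, `sequence`, `flank5`, `flank3`,
#'   `flank5_truncated`, `flank3_truncated`, `has_n`.
#' @export
extract_introns <- function(genome, annotation, flank = 8L) {
  stopifnot(is.character(genome), !is.null(names(genome)), flank >= 0L)
  tab <- if (inherits(annotation, "intron_annotation")) {
    d <- annotation$introns
    g <- annotation$genes[match(d$gene_id, annotation$genes$gene_id), ]
    data.frame(gene_id = d$gene_id, seq_id = g$seq_id,
               start = d$start, end = d$end, strand = g$strand,
               stringsAsFactors = FALSE)
  } else {
    annotation
  }
  n <- nrow(tab)
  empty <- data.frame(
    gene_id = character(), seq_id = character(), start = integer(),
    end = integer(), strand = character(), length = integer(),
    sequence = character(), flank5 = character(), flank3 = character(),
    flank5_truncated = logical(), flank3_truncated = logical(),
    has_n = logical(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  missing_seq <- setdiff(unique(tab$seq_id), names(genome))
  if (length(missing_seq)) {
    stop("seq_id not present in genome: ", paste(missing_seq, collapse = ", "))
  }
  seq_len <- nchar(genome)[tab$seq_id]
  oob <- tab$start < 1L | tab$end > seq_len | tab$start > tab$end
  if (any(oob)) {
    stop("intron interval out of sequence bounds for gene(s): ",
         paste(unique(tab$gene_id[oob]), collapse = ", "))
  }

  rows <- lapply(seq_len(n), function(i) {
    chrom <- genome[[tab$seq_id[i]]]
    s <- tab$start[i]; e <- tab$end[i]
    L <- nchar(chrom)
    body <- substr(chrom, s, e)
    up <- substr(chrom, max(1L, s - flank), s - 1L)     # plus-strand left
    down <- substr(chrom, e + 1L, min(L, e + flank))    # plus-strand right
    if (tab$strand[i] == "+") {
      f5 <- up; f3 <- down
    } else {
      body <- revcomp_dna(body)
      f5 <- revcomp_dna(down)
      f3 <- revcomp_dna(up)
    }
    data.frame(
      gene_id = tab$gene_id[i], seq_id = tab$seq_id[i],
      start = s, end = e, strand = tab$strand[i],
      length = e - s + 1L,
      sequence = dna_to_rna(body),
      flank5 = dna_to_rna(f5), flank3 = dna_to_rna(f3),
      flank5_truncated = nchar(f5) < flank,
      flank3_truncated = nchar(f3) < flank,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$has_n <- grepl("N", out$sequence, fixed = TRUE)
  if (any(out$has_n)) {
    message(sum(out$has_n), " intron(s) contain N and will be excluded from ",
            "composition/logo statistics")
  }
  rownames(out) <- NULL
  out
}

#' Write extracted introns as FASTA and TSV
#'
#' Emits `introns.fasta` (RNA sequences; header `gene_id|seq_id|start-end|strand`)
#' and `introns.tsv` (all columns, tab-separated, header row) into `dir`.
#'
#' @param introns data.frame from [extract_introns()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the two file paths.
#' @export
write_intron_outputs <- function(introns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  fa <- file.path(dir, "introns.fasta")
  tsv <- file.path(dir, "introns.tsv")
  if (nrow(introns)) {
    set <- Biostrings::RNAStringSet(introns$sequence)
    names(set) <- sprintf("%s|%s|%d-%d|%s", introns$gene_id, introns$seq_id,
                          introns$start, introns$end, introns$strand)
    Biostrings::writeXStringSet(set, fa)
  } else {
    file.create(fa)
  }
  utils::write.table(introns, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, tsv = tsv))
}
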