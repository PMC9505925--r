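#' Configuration for the synthetic-genome simulator
#'
#' Defaults encode the cohort statistics of the tiny-intron genome the
#' pipeline characterizes: 18.14 percent of genes intron-containing, a
#' 92.81/7.19 mixture of 15/16-nt introns with GU...AG termini, the
#' branchpoint adenosine at the canonical position `L - 5` for 96 percent of
#' introns, 75.63 percent intron AU content, intron-containing genes longer
#' than intronless ones (lognormal around medians 1230 vs 939 nt), and a 5'
#' positional bias of intron placement (Beta(1, 3) relative offsets, mean
#' 0.25).
#'
#' @param n_genes number of genes to simulate.
#' @param intron_gene_fraction probability a gene carries introns.
#' @param introns_per_gene_prob geometric success probability; an
#'   intron-bearing gene gets `1 + rgeom(prob)` introns (capped).
#' @param max_introns_per_gene cap on introns per gene.
#' @param length_mixture named probabilities of intron lengths.
#' @param gu_ag_prob probability an intron gets canonical GU...AG termini.
#' @param bp_canonical_prob probability the branchpoint adenosine is planted
#'   at `L - 5`; otherwise it is placed uniformly elsewhere in `[4, L - 3]`
#'   and `L - 5` is forced to a non-A base.
#' @param au_content target A+U fraction of intron sequences (free positions
#'   are drawn at a compensated rate so the expected whole-intron AU equals
#'   this after the fixed termini/branchpoint bases); also used for exonic
#'   and intergenic sequence.
#' @param bias_shape Beta shape parameters of the relative intron-offset
#'   distribution (shape1 < shape2 skews toward the 5' end).
#' @param introned_meanlog,intronless_meanlog,gene_sdlog lognormal
#'   parameters of exonic gene length for the two gene classes.
#' @param exonic_range clamp (nt) on exonic gene length.
#' @param genes_per_scaffold genes per simulated scaffold.
#' @param spacer_range intergenic spacer length range (nt).
#' @param seed RNG seed; a fixed seed makes the simulator byte-reproducible.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L,
                              intron_gene_fraction = 0.1814,
                              introns_per_gene_prob = 0.6,
                              max_introns_per_gene = 8L,
                              length_mixture = c("15" = 0.9281,
                                                 "16" = 0.0719),
                              gu_ag_prob = 1.0,
                              bp_canonical_prob = 0.96,
                              au_content = 0.7563,
                              bias_shape = c(1, 3),
                              introned_meanlog = log(1230),
                              intronless_meanlog = log(939),
                              gene_sdlog = 0.55,
                              exonic_range = c(400L, 50000L),
                              genes_per_scaffold = 100L,
                              spacer_range = c(100L, 300L),
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              intron_gene_fraction = intron_gene_fraction,
              introns_per_gene_prob = introns_per_gene_prob,
              max_introns_per_gene = as.integer(max_introns_per_gene),
              length_mixture = length_mixture,
              gu_ag_prob = gu_ag_prob,
              bp_canonical_prob = bp_canonical_prob,
              au_content = au_content,
              bias_shape = bias_shape,
              introned_meanlog = introned_meanlog,
              intronless_meanlog = intronless_meanlog,
              gene_sdlog = gene_sdlog,
              exonic_range = as.integer(exonic_range),
              genes_per_scaffold = as.integer(genes_per_scaffold),
              spacer_range = as.integer(spacer_range),
              seed = as.integer(seed))
  probs <- c(cfg$intron_gene_fraction, cfg$introns_per_gene_prob,
             cfg$gu_ag_prob, cfg$bp_canonical_prob, cfg$au_content,
             cfg$length_mixture)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$length_mixture) - 1) > 1e-9) {
    stop("length_mixture must sum to 1")
  }
  lens <- as.integer(names(cfg$length_mixture))
  if (any(is.na(lens)) || any(lens < 8L)) {
    stop("length_mixture names must be intron lengths >= 8")
  }
  if (cfg$exonic_range[1] < max(lens) + 2L * 30L + 40L) {
    stop("infeasible config: genes too short to host an intron")
  }
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  structure(cfg, class = "simulation_config")
}

rand_dna <- function(n, au) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)),
        collapse = "")
}

# one intron in transcript-orientation DNA; AU rate of free positions is
# compensated so E[whole-intron AU] hits the configured target
make_intron_dna <- function(L, cfg) {
  p_free <- (cfg$au_content * L - 3) / (L - 5)
  p_free <- min(max(p_free, 0), 1)
  chars <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
                  prob = c(p_free / 2, p_free / 2,
                           (1 - p_free) / 2, (1 - p_free) / 2))
  if (stats::runif(1) < cfg$gu_ag_prob) {
    chars[1:2] <- c("G", "T")
    chars[(L - 1L):L] <- c("A", "G")
  }
  canon <- L - 5L
  window <- seq.int(4L, L - 3L)
  if (stats::runif(1) < cfg$bp_canonical_prob) {
    b <- canon
  } else {
    others <- setdiff(window, canon)
    b <- others[sample.int(length(others), 1L)]
    chars[canon] <- sample(c("C", "G", "T"), 1L)  # no accidental canonical A
  }
  chars[b] <- "A"
  list(dna = paste(chars, collapse = ""), bp = b)
}

#' Generate a synthetic genome with planted tiny introns
#'
#' Emits a multi-scaffold genome, a GFF3-style annotation (gene, mRNA, exon
#' and explicit intron features, so both annotation-reading modes are
#' testable) and a truth table of every planted intron.  Genes are placed on
#' both strands with random intergenic spacers; all draws come from R's RNG
#' seeded with `config$seed`, so a fixed seed reproduces the output exactly.
#'
#' @param config a `simulation_config`.
#' @return list of class `tiny_sim`: `genome` (named character vector of
#'   scaffold DNA), `gff` (a `GRanges` ready for [rtracklayer::export()]),
#'   `truth` (list of data.frames `introns`, `genes`), `config`, `run_id`.
#' @export
generate_genome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_genes
  pad <- 30L; gap <- 40L
  lens_avail <- as.integer(names(config$length_mixture))

  strand <- sample(c("+", "-"), n, replace = TRUE)
  has_int <- stats::runif(n) < config$intron_gene_fraction

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    meanlog <- if (has_int[i]) config$introned_meanlog
               else config$intronless_meanlog
    exonic_len <- as.integer(round(stats::rlnorm(1, meanlog,
                                                 config$gene_sdlog)))
    exonic_len <- min(max(exonic_len, config$exonic_range[1]),
                      config$exonic_range[2])
    introns <- list()
    if (has_int[i]) {
      cap <- max(1L, (exonic_len - 2L * pad) %/% gap)
      n_int <- min(1L + stats::rgeom(1, config$introns_per_gene_prob),
                   config$max_introns_per_gene, cap)
      r <- sort(stats::rbeta(n_int, config$bias_shape[1],
                             config$bias_shape[2]))
      pos <- pad + floor(r * (exonic_len - 2L * pad))
      if (n_int > 1L) {
        for (j in 2:n_int) pos[j] <- max(pos[j], pos[j - 1L] + gap)
      }
      ilens <- if (length(lens_avail) == 1L) rep(lens_avail, n_int) else
        sample(lens_avail, n_int, replace = TRUE,
               prob = config$length_mixture)
      introns <- lapply(seq_len(n_int), function(j) {
        c(make_intron_dna(ilens[j], config), list(pos = pos[j]))
      })
    }
    exon_dna <- rand_dna(exonic_len, config$au_content)
    # assemble transcript-orientation gene DNA with introns inserted
    if (length(introns)) {
      pieces <- character(0)
      prev <- 0L
      starts_t <- integer(length(introns))
      shift <- 0L
      for (j in seq_along(introns)) {
        pieces <- c(pieces, substr(exon_dna, prev + 1L, introns[[j]]$pos),
                    introns[[j]]$dna)
        starts_t[j] <- introns[[j]]$pos + shift + 1L
        shift <- shift + nchar(introns[[j]]$dna)
        prev <- introns[[j]]$pos
      }
      pieces <- c(pieces, substr(exon_dna, prev + 1L, exonic_len))
      gene_dna <- paste(pieces, collapse = "")
      ends_t <- starts_t + vapply(introns, function(x) nchar(x$dna),
                                  integer(1)) - 1L
    } else {
      gene_dna <- exon_dna
      starts_t <- integer(0)
      ends_t <- integer(0)
    }
    genes[[i]] <- list(
      gene_id = sprintf("g%04d", i), strand = strand[i],
      dna = gene_dna, exonic_len = exonic_len,
      intron_start_t = starts_t, intron_end_t = ends_t,
      intron_dna = vapply(introns, `[[`, character(1), "dna"),
      intron_bp = vapply(introns, `[[`, integer(1), "bp"))
  }

  # place genes on scaffolds with intergenic spacers
  n_scaff <- ceiling(n / config$genes_per_scaffold)
  genome <- character(0)
  truth_introns <- list()
  truth_genes <- list()
  gff_rows <- list()
  gi <- 0L
  for (s in seq_len(n_scaff)) {
    seq_id <- sprintf("scaffold_%03d", s)
    idx <- seq.int((s - 1L) * config$genes_per_scaffold + 1L,
                   min(s * config$genes_per_scaffold, n))
    parts <- character(0)
    cursor <- 0L
    for (i in idx) {
      g <- genes[[i]]
      spacer_len <- sample(config$spacer_range[1]:config$spacer_range[2], 1L)
      parts <- c(parts, rand_dna(spacer_len, config$au_content))
      gstart <- cursor + spacer_len + 1L
      glen <- nchar(g$dna)
      gend <- gstart + glen - 1L
      parts <- c(parts, if (g$strand == "+") g$dna else revcomp_dna(g$dna))
      cursor <- gend
      ni <- length(g$intron_start_t)
      if (ni) {
        if (g$strand == "+") {
          istart <- gstart + g$intron_start_t - 1L
          iend <- gstart + g$intron_end_t - 1L
        } else {
          istart <- gstart + (glen - g$intron_end_t)
          iend <- gstart + (glen - g$intron_start_t)
        }
        ord <- order(istart)
        truth_introns[[length(truth_introns) + 1L]] <- data.frame(
          gene_id = g$gene_id, seq_id = seq_id,
          start = istart[ord], end = iend[ord], strand = g$strand,
          length = nchar(g$intron_dna)[ord],
          sequence = dna_to_rna(g$intron_dna)[ord],
          bp_position = g$intron_bp[ord],
          bp_canonical = g$intron_bp[ord] ==
            nchar(g$intron_dna)[ord] - 5L,
          stringsAsFactors = FALSE)
      }
      truth_genes[[length(truth_genes) + 1L]] <- data.frame(
        gene_id = g$gene_id, seq_id = seq_id, start = gstart, end = gend,
        strand = g$strand, gene_length = glen, exonic_length = g$exonic_len,
        n_introns = ni, stringsAsFactors = FALSE)
      # GFF rows: gene, mRNA, exons (complement of introns), introns
      mrna_id <- paste0(g$gene_id, ".t1")
      ints <- if (ni) truth_introns[[length(truth_introns)]] else NULL
      exon_bounds <- if (ni) {
        lo <- c(gstart, ints$end + 1L)
        hi <- c(ints$start - 1L, gend)
        data.frame(start = lo, end = hi)
      } else data.frame(start = gstart, end = gend)
      gff_rows[[length(gff_rows) + 1L]] <- data.frame(
        seq_id = seq_id,
        type = c("gene", "mRNA", rep("exon", nrow(exon_bounds)),
                 rep("intron", ni)),
        start = c(gstart, gstart, exon_bounds$start,
                  if (ni) ints$start else integer(0)),
        end = c(gend, gend, exon_bounds$end,
                if (ni) ints$end else integer(0)),
        strand = g$strand,
        ID = c(g$gene_id, mrna_id, rep(NA_character_, nrow(exon_bounds) + ni)),
        Parent = c(NA_character_, g$gene_id,
                   rep(mrna_id, nrow(exon_bounds) + ni)),
        stringsAsFactors = FALSE)
      gi <- gi + 1L
    }
    parts <- c(parts, rand_dna(sample(config$spacer_range[1]:
                                        config$spacer_range[2], 1L),
                               config$au_content))
    genome[[seq_id]] <- paste(parts, collapse = "")
  }

  gff_df <- do.call(rbind, gff_rows)
  gr <- GenomicRanges::GRanges(
    seqnames = gff_df$seq_id,
    ranges = IRanges::IRanges(gff_df$start, gff_df$end),
    strand = gff_df$strand)
  S4Vectors::mcols(gr)$source <- "tinyintron_sim"
  S4Vectors::mcols(gr)$type <- gff_df$type
  S4Vectors::mcols(gr)$ID <- gff_df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(gff_df$Parent, function(p) if (is.na(p)) character(0) else p))

  ti <- if (length(truth_introns)) do.call(rbind, truth_introns) else
    data.frame(gene_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               length = integer(), sequence = character(),
               bp_position = integer(), bp_canonical = logical())
  rownames(ti) <- NULL
  tg <- do.call(rbind, truth_genes)
  rownames(tg) <- NULL
  run_id <- sprintf("tinysim-seed%d-n%d", config$seed, config$n_genes)
  structure(list(genome = genome, gff = gr,
                 truth = list(introns = ti, genes = tg),
                 config = config, run_id = run_id),
            class = "tiny_sim")
}

#' @export
print.tiny_sim <- function(x, ...) {
  cat(sprintf(
    "tiny_sim %s: %d scaffold(s), %d genes, %d planted introns\n",
    x$run_id, length(x$genome), nrow(x$truth$genes), nrow(x$truth$introns)))
  invisible(x)
}

#' Write a simulated genome to disk
#'
#' Emits `genome.fasta`, `annotation.gff3`, `truth_introns.tsv`,
#' `truth_genes.tsv` and `config.json` into `dir`.  The truth files are
#' labelled synthetic via the run id embedded in `config.json`.
#'
#' @param sim a `tiny_sim` from [generate_genome()].
#' @param dir output directory (created if absent).
#' @return invisibly, named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tiny_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "annotation.gff3")
  tsv_i <- file.path(dir, "truth_introns.tsv")
  tsv_g <- file.path(dir, "truth_genes.tsv")
  cfg <- file.path(dir, "config.json")
  set <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(set, fa)
  rtracklayer::export(sim$gff, gff, format = "gff3")
  utils::write.table(sim$truth$introns, tsv_i, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$genes, tsv_g, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(unclass(sim$config), list(run_id = sim$run_id)),
                       cfg, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gff = gff, truth_introns = tsv_i,
              truth_genes = tsv_g, config = cfg))
}

#' Compare pipeline output against the simulator's planted truth
#'
#' @param truth the `truth` element of a `tiny_sim` (or its `introns`
#'   data.frame).
#' @param introns extracted introns from [extract_introns()].
#' @param bp_calls optional data.frame from [call_branchpoints()] on the same
#'   introns; enables branchpoint recovery reporting.
#' @return list with `n_truth`, `n_extracted`, `coordinate_recovery`,
#'   `sequence_recovery` and (when `bp_calls` given) `bp_recovery`, each the
#'   exact-match fraction over planted introns.
#' @export
verify_truth <- function(truth, introns, bp_calls = NULL) {
  ti <- if (is.data.frame(truth)) truth else truth$introns
  id_t <- attr(ti, "run_id"); id_p <- attr(introns, "run_id")
  if (!is.null(id_t) && !is.null(id_p) && !identical(id_t, id_p)) {
    stop("verify_truth: truth and pipeline output come from different runs")
  }
  key <- function(d) paste(d$gene_id, d$seq_id, d$start, d$end, d$strand)
  hit <- match(key(ti), key(introns))
  coord <- !is.na(hit)
  seq_ok <- coord
  seq_ok[coord] <- ti$sequence[coord] == introns$sequence[hit[coord]]
  out <- list(n_truth = nrow(ti), n_extracted = nrow(introns),
              coordinate_recovery = mean(coord),
              sequence_recovery = mean(seq_ok))
  if (!is.null(bp_calls)) {
    bp_hit <- match(key(ti), key(bp_calls))
    ok <- !is.na(bp_hit) &
      !is.na(bp_calls$bp_position[bp_hit]) &
      bp_calls$bp_position[bp_hit] == ti$bp_position
    out$bp_recovery <- mean(ok)
  }
  out
}
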