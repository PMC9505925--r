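#' Run the whole intron-characterization pipeline
#'
#' Executes extraction -> intron features -> gene features -> pairing model
#' (for the top-ranked unique intron) over a genome FASTA and a GFF3
#' annotation, writes all stage outputs plus a merged `summary.json` into
#' `out_dir`, and returns the summary.  Every percentage in the summary
#' carries its numerator and denominator alongside the rounded value.  All
#' stages are deterministic; any stage failure aborts with an error naming
#' the stage (outputs of completed stages are retained).
#'
#' @param fasta path to the genome FASTA.
#' @param gff path to the GFF3 annotation.
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param mode intron source for [read_annotation()].
#' @param flank exonic flank width (nt) for extraction and the PFM.
#' @param pfm_flank flanking positions per side in the PFM.
#' @param bp_window fallback search window of [call_branchpoint()].
#' @param bias_bins histogram bins for [positional_bias()].
#' @param weights pairing weights for [network_report()].
#' @return list of class `tinyintron_summary` (schema in
#'   `$schema_version`).
#' @export
run_all <- function(fasta, gff, out_dir = NULL,
                    mode = c("explicit-introns", "exon-gaps"),
                    flank = 8L, pfm_flank = 3L, bp_window = c(6L, 2L),
                    bias_bins = 20L, weights = default_pair_weights()) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  genome <- stage("read_genome", read_genome(fasta))
  ann <- stage("read_annotation", read_annotation(gff, mode))
  introns <- stage("extract_introns", extract_introns(genome, ann, flank))
  if (nrow(introns) == 0L) stop("stage 'extract_introns' failed: no introns")

  lengths <- stage("classify_lengths", classify_lengths(introns))
  termini <- stage("terminal_dinucleotides", terminal_dinucleotides(introns))
  pfms <- stage("build_pfm", lapply(
    stats::setNames(lengths$length, paste0("L", lengths$length)),
    function(L) build_pfm(introns, L, flank = min(pfm_flank, flank))))
  calls <- stage("call_branchpoints",
                 call_branchpoints(introns, window = bp_window))
  bp_dist <- stage("bp_position_distribution",
                   bp_position_distribution(calls, nrow(introns)))
  comp <- stage("composition", composition(introns))
  uniq <- stage("tally_unique_introns",
                tally_unique_introns(introns, "class"))
  top_call <- call_branchpoint(uniq$sequence[1], window = bp_window)
  lariat <- stage("lariat_geometry", if (!is.na(top_call$position))
    lariat_geometry(uniq$sequence[1], top_call) else NULL)
  gene_sum <- stage("summarize_genes", summarize_genes(ann))
  glen_int <- ann$genes$gene_length[ann$genes$n_introns > 0L]
  glen_no <- ann$genes$gene_length[ann$genes$n_introns == 0L]
  ttest <- stage("student_t_test",
                 if (length(glen_int) >= 2L && length(glen_no) >= 2L)
                   student_t_test(glen_int, glen_no, "pooled") else NULL)
  bias <- stage("positional_bias",
                if (nrow(ann$introns)) positional_bias(ann, bias_bins)
                else NULL)
  top_row <- introns[match(uniq$sequence[1], introns$sequence), ]
  pairing <- stage("network_report", if (!is.na(top_call$position))
    network_report(top_row, bp = top_call, weights = weights) else NULL)

  summary <- list(
    schema_version = "1.0",
    inputs = list(fasta = fasta, gff = gff, mode = mode, flank = flank,
                  bp_window = bp_window, bias_bins = bias_bins),
    n_introns = nrow(introns),
    length_distribution = lengths,
    terminal_dinucleotides = list(gu_ag_fraction = termini$gu_ag_fraction,
                                  n_used = termini$n_used,
                                  pairs = utils::head(termini$pairs, 10L)),
    bp_distribution = list(table = bp_dist,
                           no_call = attr(bp_dist, "no_call"),
                           total = attr(bp_dist, "total")),
    composition = list(au_pooled_percent = comp$au_pooled_percent,
                       au_mean_percent = comp$au_mean_percent,
                       n_used = comp$n_used, n_excluded = comp$n_excluded),
    unique_introns = utils::head(uniq, 10L),
    lariat = if (!is.null(lariat)) unclass(lariat),
    genes = list(n_introned = gene_sum$n_introned,
                 n_intronless = gene_sum$n_intronless,
                 percent_introned = gene_sum$percent_introned,
                 introns_per_gene = gene_sum$introns_per_gene,
                 gene_length = list(
                   median_introned = if (length(glen_int))
                     stats::median(glen_int),
                   median_intronless = if (length(glen_no))
                     stats::median(glen_no)),
                 t_test = if (!is.null(ttest)) unclass(ttest)),
    positional_bias = if (!is.null(bias))
      list(mean_r = bias$mean_r, histogram = bias$histogram),
    pairing = if (!is.null(pairing)) list(
      intron = pairing$intron, bp = pairing$bp,
      diagram = format(pairing),
      alignments = lapply(pairing$alignments, function(a)
        list(motif = a$motif_name, score = a$score, offset = a$offset,
             bulge = a$bulge, pairs = a$pairs)))
  )
  class(summary) <- "tinyintron_summary"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_intron_outputs(introns, out_dir)
    utils::write.table(calls, file.path(out_dir, "bp_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(pfms)) {
      p <- pfms[[nm]]
      utils::write.table(
        data.frame(position = p$positions, t(p$freq), info = p$info,
                   check.names = FALSE),
        file.path(out_dir, paste0("pfm_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(bias)) {
      utils::write.table(bias$ratios, file.path(out_dir, "bias.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(render_summary(summary), file.path(out_dir, "summary.txt"),
               useBytes = TRUE)
  }
  summary
}

fmt_pct_line <- function(label, count, total, pct) {
  sprintf("  %-18s %6d / %-6d  (%.2f%%)", label, count, total, pct)
}

#' Render a pipeline summary as a plain-text report
#'
#' @param summary a `tinyintron_summary` from [run_all()].
#' @return character vector of report lines.
#' @export
render_summary <- function(summary) {
  s <- summary
  ld <- s$length_distribution
  bp <- s$bp_distribution
  out <- c(
    sprintf("tinyintron summary (schema %s)", s$schema_version),
    sprintf("introns analyzed: n=%d", s$n_introns),
    "",
    "intron length classes:",
    if (nrow(ld)) fmt_pct_line(sprintf("%d nt:", ld$length), ld$count,
                               s$n_introns, ld$share) else "  n=0",
    sprintf("GU...AG introns: %.2f%% of %d", 100 * s$terminal_dinucleotides$gu_ag_fraction,
            s$terminal_dinucleotides$n_used),
    "",
    "branchpoint adenosine positions (denominator: all introns):",
    if (nrow(bp$table)) fmt_pct_line(sprintf("position %d:", bp$table$position),
                                     bp$table$count, bp$total,
                                     bp$table$percent) else "  n=0",
    sprintf("  no-call: %d", bp$no_call),
    "",
    sprintf("AU content: %.2f%% pooled, %.2f%% mean of introns (n=%d)",
            s$composition$au_pooled_percent, s$composition$au_mean_percent,
            s$composition$n_used),
    "",
    "most abundant intron sequences:",
    if (nrow(s$unique_introns)) sprintf(
      "  %-20s %5d  (%.2f%% of %d-nt class)", s$unique_introns$sequence,
      s$unique_introns$count, s$unique_introns$percent,
      s$unique_introns$length) else "  n=0",
    if (!is.null(s$lariat)) sprintf(
      "lariat of top intron: %d-nt loop, %d-nt 3′ tail",
      s$lariat$loop_length, s$lariat$tail_length),
    "",
    "genes:",
    fmt_pct_line("intron-containing:", s$genes$n_introned,
                 s$genes$n_introned + s$genes$n_intronless,
                 s$genes$percent_introned),
    if (!is.null(s$genes$gene_length$median_introned)) sprintf(
      "  median gene length: %g (introned) vs %g (intronless)",
      s$genes$gene_length$median_introned,
      s$genes$gene_length$median_intronless),
    if (!is.null(s$genes$t_test)) sprintf(
      "  %s t-test: t=%.3f, df=%.1f, p=%.3g", s$genes$t_test$variant,
      s$genes$t_test$t, s$genes$t_test$df, s$genes$t_test$p),
    if (!is.null(s$positional_bias)) sprintf(
      "  positional bias: mean 5′ offset ratio r = %.3f", s$positional_bias$mean_r),
    "",
    if (!is.null(s$pairing)) c("snRNA pairing network of top intron:",
                               s$pairing$diagram)
  )
  unlist(out[!vapply(out, is.null, logical(1))])
}

#' @export
print.tinyintron_summary <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
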