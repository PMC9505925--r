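#' Gene-cohort summary: intron-containing fraction and introns per gene
#'
#' @param annotation an `intron_annotation` from [read_annotation()] or its
#'   `genes` data.frame (needs `n_introns`).
#' @return list with `n_introned`, `n_intronless`, `percent_introned`
#'   (half-up, 2 decimals; 6218 of 34,282 genes gives 18.14),
#'   `introns_per_gene` (data.frame `k`, `count`, k = 0 bin included).
#' @export
summarize_genes <- function(annotation) {
  genes <- if (inherits(annotation, "intron_annotation")) annotation$genes
           else annotation
  if (nrow(genes) == 0L) stop("summarize_genes: no genes")
  k <- genes$n_introns
  tab <- table(k)
  list(
    n_introned = sum(k > 0L),
    n_intronless = sum(k == 0L),
    percent_introned = percent_share(sum(k > 0L), nrow(genes)),
    introns_per_gene = data.frame(k = as.integer(names(tab)),
                                  count = as.integer(tab))
  )
}

#' Two-tailed unpaired Student's t-test (pooled or Welch)
#'
#' A thin wrapper over [stats::t.test()] (`var.equal = TRUE` for the pooled
#' variant) that additionally reports group medians — useful when the center
#' of interest is the median (as for skewed gene-length distributions) while
#' the significance test is a t-test — and defines the degenerate
#' zero-variance cases that `t.test()` refuses: both samples constant with
#' equal means gives `t = 0, p = 1`; constant with unequal means gives a
#' signed infinite `t` and `p = 0`.
#'
#' @param x,y numeric samples (each of size >= 2, finite).
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @return list of class `t_test_result`: `t`, `df`, `p`, `mean_x`, `mean_y`,
#'   `median_x`, `median_y`, `variant`.
#' @export
student_t_test <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  base <- list(mean_x = mean(x), mean_y = mean(y),
               median_x = stats::median(x), median_y = stats::median(y),
               variant = variant)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    res <- if (d == 0) list(t = 0, df = length(x) + length(y) - 2L, p = 1)
           else list(t = sign(d) * Inf, df = length(x) + length(y) - 2L, p = 0)
  } else {
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(c(res, base), class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf(
    "%s t-test: t = %.4f, df = %.2f, p = %.3g\n  means %.2f vs %.2f; medians %.2f vs %.2f\n",
    x$variant, x$t, x$df, x$p, x$mean_x, x$mean_y, x$median_x, x$median_y))
  invisible(x)
}

#' 5' positional bias of introns within genes
#'
#' For each intron the relative start position `r` in transcript orientation
#' is computed: on `+` genes `r = (intron_start - gene_start) / gene_length`,
#' on `-` genes `r = (gene_end - intron_end) / gene_length`.  `r = 0` is the
#' first transcribed position; a cohort mean below 0.5 indicates 5' bias.
#'
#' @param annotation an `intron_annotation` from [read_annotation()].
#' @param bins number of equal-width histogram bins over \[0, 1\].
#' @return list with `ratios` (data.frame `gene_id`, `intron_index`, `r`),
#'   `mean_r`, `histogram` (data.frame `bin_lo`, `bin_hi`, `count`).
#' @export
positional_bias <- function(annotation, bins = 20L) {
  genes <- annotation$genes
  d <- annotation$introns
  if (nrow(d) == 0L) stop("positional_bias: annotation has no introns")
  g <- genes[match(d$gene_id, genes$gene_id), ]
  if (any(g$gene_length <= 0L)) stop("gene of length 0")
  r <- ifelse(g$strand == "+",
              (d$start - g$start) / g$gene_length,
              (g$end - d$end) / g$gene_length)
  stopifnot(all(r >= 0), all(r <= 1))
  idx <- stats::ave(seq_along(r), d$gene_id, FUN = seq_along)
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(r, breaks, rightmost.closed = TRUE), bins)
  list(
    ratios = data.frame(gene_id = d$gene_id, intron_index = idx, r = r,
                        stringsAsFactors = FALSE),
    mean_r = mean(r),
    histogram = data.frame(bin_lo = breaks[-length(breaks)],
                           bin_hi = breaks[-1L],
                           count = tabulate(bin, nbins = bins))
  )
}
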