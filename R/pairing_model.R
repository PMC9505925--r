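#' Classify one RNA base pair
#'
#' Taxonomy used throughout the duplex model: Watson-Crick (`A-U`, `G-C`),
#' wobble (`G-U`), and the non-canonical `U-U` pair that U-rich branchpoint
#' regions can form; every other combination is unpaired.  Classification is
#' symmetric in its arguments.
#'
#' @param b1,b2 single RNA bases (`A`, `C`, `G`, `U`); vectors are recycled
#'   pairwise.
#' @return character vector with values `"WC"`, `"WOBBLE"`,
#'   `"NONCANONICAL_UU"` or `"NONE"`.
#' @export
pair_type <- function(b1, b2) {
  valid <- c("A", "C", "G", "U")
  bad <- !(b1 %in% valid) | !(b2 %in% valid)
  if (any(bad)) warning("non-ACGU base(s) in pair_type; classified as NONE")
  key <- paste0(pmin(b1, b2), pmax(b1, b2))  # order-free lookup
  out <- rep("NONE", length(key))
  out[key %in% c("AU", "CG")] <- "WC"
  out[key == "GU"] <- "WOBBLE"
  out[key == "UU"] <- "NONCANONICAL_UU"
  out[bad] <- "NONE"
  out
}

#' Built-in snRNA recognition motifs
#'
#' The intron-recognition sequences of the spliceosomal snRNAs used by the
#' duplex model: the U1 snRNA 5' splice-site binding region `ACUUACCU`, the
#' U2 snRNA branchpoint-binding motif `GUAGUA`, and the U6 snRNA ACAGAGA box.
#' All sequences are RNA, written 5'->3'.
#'
#' @return named character vector of motif sequences.
#' @export
snrna_motifs <- function() {
  c(U1_5p = "ACUUACCU",
    U2_BP = "GUAGUA",
    U6_ACAGAGA = "ACAGAGA")
}

resolve_motif <- function(motif) {
  reg <- snrna_motifs()
  if (length(motif) == 1L && motif %in% names(reg)) {
    list(name = motif, sequence = reg[[motif]])
  } else if (is.list(motif)) {
    list(name = motif$name %||% "custom", sequence = toupper(motif$sequence))
  } else {
    list(name = "custom", sequence = toupper(motif))
  }
}

default_pair_weights <- function() {
  c(WC = 2, WOBBLE = 1, NONCANONICAL_UU = 1, NONE = 0)
}

#' Best antiparallel duplex between an intron region and an snRNA motif
#'
#' Exhaustively scores every antiparallel offset of the motif (3'->5')
#' against the region (5'->3').  An optional single bulge excludes one region
#' position (the branchpoint adenosine) from pairing; the motif continues
#' across it.  Score is the sum of per-pair weights; unpaired (NONE)
#' combinations contribute 0 and no gaps other than the single bulge are
#' allowed.  Ties are broken by the smallest offset, then the longest
#' contiguous paired run.
#'
#' @param region RNA string (5'->3'), length >= 2.
#' @param motif a registry name from [snrna_motifs()], an RNA string, or a
#'   list with `name`/`sequence`.
#' @param weights named non-negative weights per pair type; `NONE` is fixed
#'   at 0.
#' @param bulge_at optional 1-based region position excluded from pairing.
#' @return object of class `duplex_alignment`: list with `offset`, `pairs`
#'   (data.frame `region_pos`, `region_base`, `motif_pos`, `motif_base`,
#'   `type`), `bulge`, `score`, `region`, `motif_name`, `motif_seq`.
#' @export
duplex_align <- function(region, motif, weights = default_pair_weights(),
                         bulge_at = NULL) {
  region <- toupper(region)
  if (nchar(region) < 2L) stop("duplex_align: region shorter than 2 nt")
  m <- resolve_motif(motif)
  w <- default_pair_weights()
  w[names(weights)] <- weights
  if (any(w < 0)) stop("duplex_align: weights must be non-negative")
  w["NONE"] <- 0

  rchars <- seq_chars(region)
  rpos <- seq_along(rchars)
  if (!is.null(bulge_at)) {
    if (bulge_at < 1L || bulge_at > length(rchars)) {
      stop("duplex_align: bulge position outside region")
    }
    keep <- rpos != bulge_at
    rchars <- rchars[keep]
    rpos <- rpos[keep]
  }
  Rc <- length(rchars)
  mchars <- seq_chars(m$sequence)
  M <- length(mchars)
  mrev <- rev(mchars)                     # index j: motif position M - j + 1

  best <- NULL
  for (d in seq.int(1L - M, Rc - 1L)) {
    i <- seq.int(max(1L, d + 1L), min(Rc, d + M))
    j <- i - d
    type <- pair_type(rchars[i], mrev[j])
    score <- sum(w[type])
    paired <- type != "NONE"
    run <- if (any(paired)) max(rle(paired)$lengths[rle(paired)$values]) else 0L
    cand <- list(d = d, i = i, j = j, type = type, score = score, run = run)
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && (d < best$d ||
                                 (d == best$d && run > best$run)))) {
      best <- cand
    }
  }
  pairs <- data.frame(
    region_pos = rpos[best$i],
    region_base = rchars[best$i],
    motif_pos = M - best$j + 1L,
    motif_base = mchars[M - best$j + 1L],
    type = best$type,
    stringsAsFactors = FALSE)
  structure(list(offset = best$d, pairs = pairs,
                 bulge = bulge_at %||% NA_integer_,
                 score = unname(best$score),
                 region = region, motif_name = m$name,
                 motif_seq = m$sequence),
            class = "duplex_alignment")
}

#' Branch helix between the branchpoint region and the U2 snRNA motif
#'
#' Pairs the branchpoint region of an intron with the U2 branchpoint-binding
#' motif (GUAGUA) while the branchpoint adenosine bulges out of the helix:
#' the region is the window `b - window[1] .. b + window[2]` (clamped to the
#' intron) around the called branchpoint `b`, and position `b` is excluded
#' from pairing.
#'
#' @param intron intron RNA sequence (5'->3').
#' @param bp a `bp_call` from [call_branchpoint()] or a 1-based position.
#' @param motif U2 motif (default the registry `U2_BP`).
#' @param window integer pair: nt upstream / downstream of `b` in the region.
#' @param weights per-pair-type weights, as in [duplex_align()].
#' @return `duplex_alignment` whose `pairs` use intron coordinates and whose
#'   `bulge` is `b`; extra fields `region_start`, `bp_position`.
#' @export
branch_helix <- function(intron, bp, motif = "U2_BP", window = c(4L, 2L),
                         weights = default_pair_weights()) {
  if (inherits(bp, "bp_call")) bp <- bp$position
  if (is.null(bp) || is.na(bp)) stop("branch_helix: branchpoint is a no-call")
  L <- nchar(intron)
  if (bp < 1L || bp > L) stop("branch_helix: bulge position outside region")
  lo <- max(1L, bp - window[1]); hi <- min(L, bp + window[2])
  region <- substr(intron, lo, hi)
  aln <- duplex_align(region, motif, weights = weights,
                      bulge_at = bp - lo + 1L)
  # report pairs and bulge in intron coordinates
  aln$pairs$region_pos <- aln$pairs$region_pos + lo - 1L
  aln$bulge <- bp
  aln$region_start <- lo
  aln$bp_position <- bp
  aln
}

#' RNA-RNA interaction network of one intron in the assembled active site
#'
#' Computes the best duplexes formed around one intron before the first
#' transesterification: the U1 snRNA 5' region and the U6 ACAGAGA box against
#' the 5' splice-site region (3' end of the upstream exon plus the intron 5'
#' end), and the U2 branchpoint motif against the branchpoint region with the
#' branchpoint adenosine bulged out.  U5 loop 1 contacts the 5' exon in the
#' assembled spliceosome but is noted informationally only, without a scored
#' duplex.
#'
#' @param intron intron RNA sequence (5'->3') or one row of
#'   [extract_introns()] output (then `flank5` is taken from it).
#' @param bp a `bp_call` or 1-based branchpoint position; default calls it.
#' @param flank5 exonic RNA immediately upstream of the intron (may be "").
#' @param ss5_exon_width,ss5_intron_width how many exonic / intronic nt form
#'   the 5' splice-site region (defaults 3 and 6).
#' @param branch_window window around the branchpoint for the branch helix.
#' @param weights per-pair-type weights, as in [duplex_align()].
#' @return object of class `pairing_network`: list with `intron`, `bp`,
#'   `ss5_region`, `ss5_exon_len`, `alignments` (named list `U1_5p`,
#'   `U6_ACAGAGA`, `U2_BP`), `u5_note`.
#' @export
network_report <- function(intron, bp = NULL, flank5 = "",
                           ss5_exon_width = 3L, ss5_intron_width = 6L,
                           branch_window = c(4L, 2L),
                           weights = default_pair_weights()) {
  if (is.data.frame(intron)) {
    stopifnot(nrow(intron) == 1L)
    flank5 <- intron$flank5 %||% ""
    intron <- intron$sequence
  }
  intron <- toupper(intron)
  if (is.null(bp)) bp <- call_branchpoint(intron)
  if (inherits(bp, "bp_call")) bp <- bp$position
  if (is.null(bp) || is.na(bp)) stop("network_report: branchpoint is a no-call")

  exon <- if (nzchar(flank5)) {
    substr(flank5, max(1L, nchar(flank5) - ss5_exon_width + 1L), nchar(flank5))
  } else ""
  ss5 <- paste0(exon, substr(intron, 1L, min(ss5_intron_width, nchar(intron))))

  alns <- list(
    U1_5p = duplex_align(ss5, "U1_5p", weights = weights),
    U6_ACAGAGA = duplex_align(ss5, "U6_ACAGAGA", weights = weights),
    U2_BP = branch_helix(intron, bp, window = branch_window,
                         weights = weights)
  )
  structure(list(
    intron = intron, bp = bp, ss5_region = ss5,
    ss5_exon_len = nchar(exon),
    alignments = alns,
    u5_note = paste("U5 snRNA loop 1 contacts the 5' exon in the assembled",
                    "spliceosome (not scored: no loop sequence modeled)")
  ), class = "pairing_network")
}

pair_glyph <- function(type) {
  c(WC = "|", WOBBLE = ":", NONCANONICAL_UU = "•", NONE = " ")[type]
}

render_alignment <- function(aln, region_label) {
  width <- nchar(aln$region)
  off <- (aln$region_start %||% 1L) - 1L
  motif_line <- rep(" ", width)
  glyph_line <- rep(" ", width)
  for (k in seq_len(nrow(aln$pairs))) {
    col <- aln$pairs$region_pos[k] - off
    motif_line[col] <- aln$pairs$motif_base[k]
    glyph_line[col] <- pair_glyph(aln$pairs$type[k])
  }
  bulge_mark <- rep(" ", width)
  if (!is.na(aln$bulge)) bulge_mark[aln$bulge - off] <- "^"
  pad <- function(s) sprintf("  %-22s", s)
  lines <- c(
    sprintf("%s (motif %s, 3'->5' across): score %g, offset %d",
            aln$motif_name, aln$motif_seq, aln$score, aln$offset),
    paste0(pad("snRNA"), paste(motif_line, collapse = "")),
    paste0(pad(""), paste(glyph_line, collapse = "")),
    paste0(pad(region_label), aln$region))
  if (!is.na(aln$bulge)) {
    lines <- c(lines, paste0(pad("bulged BP-A"),
                             paste(bulge_mark, collapse = "")))
  }
  lines
}

#' Render a pairing network as a text diagram
#'
#' Pair glyphs: `|` Watson-Crick, `:` wobble, `•` non-canonical U-U.
#'
#' @param x a `pairing_network` from [network_report()].
#' @param ... unused.
#' @return character vector of diagram lines (invisibly from `print`).
#' @export
format.pairing_network <- function(x, ...) {
  branch <- x$alignments$U2_BP
  c(sprintf("Intron (5'->3'): %s  [BP-A at %d]", x$intron, x$bp),
    sprintf("5' splice-site region: %s (last %d nt exonic)", x$ss5_region,
            x$ss5_exon_len),
    "",
    render_alignment(x$alignments$U1_5p, "5'SS region (5'->3')"),
    "",
    render_alignment(x$alignments$U6_ACAGAGA, "5'SS region (5'->3')"),
    "",
    render_alignment(branch, sprintf("branch region %d..%d",
                                     branch$region_start,
                                     branch$region_start +
                                       nchar(branch$region) - 1L)),
    "",
    paste0("note: ", x$u5_note))
}

#' @export
print.pairing_network <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(render_alignment(x, "region (5'->3')"), sep = "\n")
  invisible(x)
}
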