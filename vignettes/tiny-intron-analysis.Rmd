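---
title: "Characterizing tiny spliceosomal introns and their snRNA contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tiny spliceosomal introns and their snRNA contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tinyintron)
```

## The problem

A handful of eukaryotic genomes — most strikingly some ciliates — restrict
nearly all of their spliceosomal introns to 15 or 16 nucleotides. At that
size the intron barely accommodates the three elements the major spliceosome
recognizes: a `GU` 5′ splice site, a branchpoint adenosine (BP-A), and an
`AG` 3′ splice site. The excised intron is a lariat: a 2′–5′ bond joins the
intron's first nucleotide to the BP-A, so the circular loop spans positions
`1..b` (length `b`) and the remaining `L − b` nucleotides form a linear 3′
tail. With the BP-A at position `L − 5`, a 15-nt intron closes a 10-nt loop
and a 16-nt intron an 11-nt loop, each with a 5-nt tail.

`tinyintron` packages the full desk analysis of such a genome: extraction of
every annotated intron, cohort statistics, a t-test-based gene-length
comparison, and an explicit base-pairing model of how the U1, U2 and U6
snRNAs could engage these introns in the assembled spliceosome. A seedable
simulator generates genomes with planted intron structure, so each claim the
pipeline makes is testable against known truth.

## Pipeline model and conventions

**Coordinates.** GFF3 coordinates are 1-based inclusive, and the package
keeps that convention end to end — R's string and range machinery
(`substr`, `IRanges`) is itself 1-based inclusive, so introducing a
0-based internal layer would only add a conversion surface without a safety
benefit. Minus-strand intron sequences are reverse-complemented into
transcript orientation (and `T` mapped to `U`), while their genomic
`start`/`end` stay plus-strand; this is what lets one speak of "introns
starting with GU" regardless of strand.

**Annotation modes.** Intron intervals come either from explicit `intron`
features (resolved to genes through the `Parent` chain, intron → mRNA →
gene) or, in `exon-gaps` mode, as gaps between the merged exons of a gene.
On annotations carrying both, the modes agree (a test asserts this on the
simulator, which emits both feature types). Alternative isoforms are merged
before gap-taking; reconciling conflicting isoform-specific introns is out
of scope.

**Alphabet.** Genomes are normalized to uppercase `A/C/G/T/N`; IUPAC
ambiguity codes are folded to `N` with a warning. Introns containing `N`
are retained in counts but excluded from composition and frequency-matrix
statistics, and the exclusion is reported.

**Rounding.** Every reported percentage uses half-up rounding to two
decimals, computed from an explicit numerator and denominator that travel
with the value in `summary.json`. Two denominator conventions matter and
are fixed by the cohort arithmetic they must reproduce: branchpoint-position
percentages use *all* introns of the cohort, while unique-sequence shares
use the *length class* of the sequence.

## Branchpoint calling

The cohort structure of tiny introns motivates a deliberately simple caller:
the canonical BP-A position is `L − 5`, and when an `A` sits there it is
called with no further search. Otherwise a fallback looks for the nearest
`A` inside `[max(4, L−5−w1), min(L−3, L−5+w2)]` (defaults `w1 = 6`,
`w2 = 2`), breaking ties toward the 3′ end — the downstream position
preserves the canonical 5-nt tail geometry more closely. If the window has
no `A`, the intron is a no-call; no-calls are values, not errors, and the
distribution reports them. The window bounds keep the call clear of the
`GU`/`AG` termini. This is a positional heuristic, not a statistical motif
model: the branchpoint region of these introns shows no strong consensus,
so a PWM-based caller would mostly refit the positional prior anyway.

`lariat_geometry` is then pure arithmetic (`loop = b`, `tail = L − b`,
conserving `loop + tail = L`), with an explicit degenerate flag when
`b = L` (empty tail).

## The duplex model

The pairing model asks, for one intron: what is the best antiparallel,
gap-free duplex each snRNA recognition motif can form with its target
region? Three pair types score: Watson–Crick (A-U, G-C; weight 2), G-U
wobble (1), and the non-canonical U•U pair (1) that U-rich branchpoint
regions can offer. The weights are configurable; the defaults encode only
that a Watson–Crick pair is stronger than either non-canonical geometry,
which are treated as equally admissible. All offsets of the motif (read
3′→5′) against the region (5′→3′) are scored exhaustively; ties go to the
smallest offset, then the longest contiguous paired run. Mismatched
positions contribute zero and are rendered unpaired; the only allowed
deviation from a contiguous helix is a single bulge.

The branch helix pairs the window `b−4 .. b+2` around the called BP-A with
the U2 motif `GUAGUA` while position `b` is excluded from pairing entirely —
the bulged-adenosine geometry of the pre-catalytic branch helix. The window
is configurable and reported with every alignment, since the exact register
of the branch helix in a 15-nt intron is not observable from sequence alone.
The 5′ splice-site region offered to U1 (`ACUUACCU`) and to the U6 ACAGAGA
box is the last 3 exonic plus first 6 intronic nucleotides (both widths
configurable). U5 loop 1 contacts the 5′ exon in the assembled spliceosome,
but no loop sequence is modeled here, so the report notes the contact
without scoring it rather than inventing a sequence.

Correctness of `duplex_align` is established against an independently
written brute-force enumerator (naive nested loops over every offset and
bulge placement) for all region/motif sizes up to 8 nt.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults *are* the study conditions: 18.14% of genes
intron-containing; intron lengths 15/16 mixed 92.81/7.19; `GU…AG` termini
with probability 1; BP-A canonical at `L − 5` with probability 0.96
(otherwise uniform elsewhere in `[4, L−3]`); intron AU content 75.63%;
intron-containing genes longer than intronless ones (lognormal around
medians 1230 vs 939 nt, `sdlog` 0.55 — a realistic spread for compact
genomes); introns per gene `1 + Geometric(0.6)` capped at 8, reflecting a
cohort where most intron-bearing genes carry a single intron; and intron
placement drawn from Beta(1, 3) relative offsets (mean 0.25), a one-knob
skew that reproduces 5′ positional bias. Values not fixed by the cohort
statistics (scaffold packing of 100 genes, 100–300 nt intergenic spacers,
the geometric intron-count law, the Beta skew) are modeling choices made
once and documented here.

Two constructions keep the planted truth exact rather than approximate:

- **Composition compensation.** Fixed bases (the `GU…AG` termini and the
  BP-A) would drag realized AU content below the configured target if free
  positions were drawn at that target rate. Free positions are instead drawn
  at `p = (AU·L − 3)/(L − 5)`, so the *expected whole-intron* AU equals the
  configured value and the 3-standard-error acceptance check tests sampling
  noise, not a structural bias.
- **Canonical-fraction exactness.** When a non-canonical BP is planted,
  position `L − 5` is forced to a non-`A` base. Canonical-only calling
  (`fallback = FALSE`) therefore recovers exactly the planted canonical
  fraction, by construction.

The simulator emulates marginal statistics with i.i.d. sequence around the
planted signals. Real genomes violate this in ways that matter for some
questions: no codon structure or coding constraint in exons, no dinucleotide
autocorrelation, no splice-site-proximal composition gradients, no isoform
variation, and every gene carries exactly one mRNA. Passing the round-trip
and recovery tests therefore demonstrates that the *pipeline machinery* is
exact — coordinates, strand handling, parsing, arithmetic — not that the
branchpoint heuristic or the duplex model would achieve any particular
accuracy on a real genome.

All randomness flows from one `set.seed(config$seed)` call (the caller's RNG
state is restored afterwards), making simulator output reproducible for a
fixed seed.

## Gene-level statistics

Gene length is the genomic span `end − start + 1`: the annotation is not
guaranteed to carry UTR-resolved mRNA bounds, and span is the quantity every
GFF3 supplies. The gene-length comparison reports a two-tailed unpaired
Student's t-test (pooled variance by default, Welch available) *and* the
group medians: with skewed length distributions the median is the more
honest location summary, while the t-test supplies the conventional
significance statement. The implementation delegates to `stats::t.test`;
the degenerate zero-variance cases it refuses are defined by convention
(`t = 0, p = 1` for equal constant samples; signed infinite `t`, `p = 0`
otherwise) and the whole statistic is verified against a hand-written
closed form to 1e-9. Positional bias is strand-aware
(`r = (start − gene_start)/len` on `+`, `(gene_end − end)/len` on `−`), so
`r = 0` is always the 5′-most transcribed position; the histogram bin count
(default 20) is a display parameter only.

## Problem sizes and numerical choices

The test suite exercises the pipeline end to end on simulated genomes of
30–150 genes per scenario and one 2000-gene genome (~600 introns, ~2.5 Mb)
for the genome-scale property checks — large enough that three standard
errors of the configured marginals are tight (about 1–3 percentage points)
while the whole suite stays interactive. Frequency-matrix information
content uses log2 with the `0·log 0 := 0` convention, bounded in `[0, 2]`
bits; column frequencies are validated to sum to 1 within 1e-9. Percent
rounding carries a 1e-9 epsilon so that values sitting exactly on a .005
boundary after floating-point representation round up as intended.

## Known limitations

- The branchpoint caller is positional; it will mis-call introns whose real
  branchpoint deviates from the canonical offset yet have an `A` there.
- The duplex model is combinatorial, not thermodynamic: no stacking, no
  nearest-neighbor energies, no competition between snRNAs for overlapping
  registers.
- `exon-gaps` mode merges isoforms before inferring introns; annotations
  with mutually exclusive exons will yield the union's gaps.
- The simulator's i.i.d. background is a deliberate simplification (above);
  statistics sensitive to higher-order sequence structure should not be
  benchmarked against it.
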