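---
title: "motifscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motifscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifscape)
```

This vignette explains what `motifscape` computes, the conventions it
commits to, and why the open design points were settled the way they were.
It states no number that the test suite or `scripts/acceptance.R` does not
itself recompute.

## The problem

MEME reports discovered motifs in two machine-readable dialects. The XML
document carries the training set, the motif models and, per motif, the
*contributing sites* — the actual occurrences on the input sequences, with
0-based offsets, p-values, flanks and site letters — plus an optional
per-sequence *scanned-sites* summary. The text report repeats most of this
in fixed-format blocks, with 1-based start coordinates. Downstream work on
gene families needs exactly one thing neither dialect offers directly: a
tidy table of *which motif occurs where on which sequence*, joinable to a
phylogeny of the same sequences.

## Coordinates and the occurrence table

All coordinates in `motifscape` are **1-based inclusive** `[start, end]`,
the convention a biologist reads in the text report. XML contributing-site
offsets are converted on ingest (`start = offset + 1`,
`end = start + width − 1`); text starts are kept as printed. The invariant
`end − start + 1 = width` is asserted by the class validity and tested
across both dialects on every synthetic fixture, which makes the
conversion itself an observable contract: if either parser treated its
dialect's origin wrongly, the cross-dialect comparison would shift by one.

Contributing sites are the canonical occurrence source: they carry
p-values, flanks and site letters. The scanned-sites summary, when present
in the XML, is parsed into its own slot and never merged — the two lists
largely overlap, and merging would double-count sites.

The table is ordered deterministically (sequence name, then start, then
motif id as tie-break) so that TSV outputs are stable golden files.
P-values are written with `%.17g`, which round-trips doubles exactly.

Filtering is a conjunction of independent predicates (motif ids, site
p-value, motif E-value, motif Bayes threshold); absent predicates are
no-ops and row order is preserved. MEME does not document a comparison
direction for the Bayes threshold as a filter; `motifscape` uses
`bayes_threshold <= maxBayes`, documented on `filterOccurrences()`.
Unknown motif ids warn rather than error — selecting nothing is a
legitimate outcome of an interactive narrowing session.

## Dialect policy

Any MEME 5.x minor version is accepted; 4.x and earlier are rejected with
the found version in the message rather than parsed best-effort — the two
major versions differ in structure in ways that would fail silently.
E-values in scientific notation are normalized during parsing, including
the unicode minus some reports print. Strand is stored for nucleotide
alphabets and forced to `none` for protein; it is never inferred. In the
text dialect the Bayes threshold is read from the `log-odds matrix:` line
of the scoring-matrix block, where MEME 5 prints it.

Printed probability matrices (6 decimal places in both dialects) are
renormalized per column on ingest so the
`PositionProbabilityMatrix` validity (columns sum to 1 within 1e-9) holds
regardless of print rounding.

## Logo mathematics

For a K-letter alphabet and per-column letter probabilities `p_ik`
estimated from `n` sites,

* column entropy: `H_i = −Σ_k p_ik log2 p_ik`, with `0·log2 0 := 0`;
* information content: `R_i = log2 K − H_i − e(n)`, clipped below at 0;
* small-sample correction: `e(n) = (K − 1) / (2 ln 2 · n)` when enabled,
  0 otherwise;
* letter heights: `p_ik · R_i`, so every stack sums to its column's IC.

The correction defaults **off**, matching common logo-drawing practice;
it is exposed as a flag, and clipping (rather than drawing below the axis)
handles the negative corrected values that arise at low `n`. The default
pseudocount is 0, so logos reflect the extracted sites verbatim; `1/K` is
the documented regularized alternative. Logos are always computed from the
parsed site sequences — XML-only inputs therefore still yield logos — and
when a file also carries a printed probability matrix it is used only for
a consistency check (warning beyond 0.01 per cell), never for drawing.

Letters are rendered as filled polygons from a small stroke/arc vector
font defined in code, stretched to their exact height in bits, stacked
tallest-on-top, with the y-axis fixed at `[0, log2 K]`. Colors follow a
conventional chemistry palette (bases individually; amino acids by
hydrophobic / polar / basic / acidic class). Device fonts are never
involved, so figure geometry is reproducible across environments.

## Trees and row order

Input is restricted to Newick (the format the usual alignment + FastTree
pipeline emits); Nexus and other formats are out of scope. Trees are
treated as rooted as written, with no midpoint rooting. `leafOrder()` is a
depth-first traversal with children in **written file order** — no
ladderization by default, because figure row order depends on it; an
explicit `ladderize` flag (ascending/descending by clade size) is provided
for users who want the conventional staircase look. The rectangular layout
puts tip `i` of the leaf order at `y = i` and each internal node midway
between the extreme y of its children; x is the cumulative branch length
from the root, with absent lengths stored as 0 (zero-length branches still
stack vertically).

Tip labels are matched to sequence names by exact string equality —
the ids fed to MEME and to tree building must be the same strings, dots
included. Annotation joins and tree/table intersections never drop a name
silently: every name present on only one side gets its own warning, and an
empty intersection is an error listing both sets.

## Track figures

The motif-location map shares one x-axis in residues/bases across all
tracks (no per-row normalization), so shorter sequences visibly end
earlier. Every table row becomes exactly one box; the motif-to-color
assignment is a pure function of the sorted motif-id set (stable across
reruns and subsets), with a 12-color categorical palette that cycles with
a warning beyond 12 motifs. Overlapping boxes on one row are drawn with
the later-starting box on top plus translucency; minus-strand occurrences
carry a `<` glyph; protein occurrences carry none. With a tree, the tree
panel sits left, sequence names sit between the panels, and both panels
share row y-coordinates. The resolved geometry (`TrackLayout`) is a
first-class object serializable to JSON, so tests and external tools
assert on geometry rather than on rendered pixels — SVG output across
cairo versions is not byte-stable, but the geometry is.

## The synthetic-data generator

`motifSimSpec()` defaults describe the study condition the package is
built around: a ZOOPS protein scan of 20 sequences (lengths 100–500) for
10 motifs of widths 4–7 — the shape of a typical transcription-factor
family analysis. Per motif and sequence, a site is planted with
probability 0.6 (a realistic ZOOPS hit rate for a family-wide motif;
at most one site per sequence per motif, so same-motif sites never
overlap). Site letters follow a degenerate-consensus model (consensus
letter with probability 0.75, otherwise uniform over the rest), which
yields informative but non-trivial logos. Planted p-values are log-uniform
in [1e-12, 1e-2] and e-values are nsites-scaled aggregates — format
realistic, not statistically faithful to MEME's model, which is explicitly
out of scope.

Planted numeric values are quantized through the exact formats the writers
print (`%.2e` for p-values, `%.1e` for e-values, `%.5f` for Bayes
thresholds; background frequencies to 6 decimals with the last letter
absorbing the remainder so they sum exactly to 1). This makes
`parse(write(truth))` reproduce the truth **bit-exactly**, which is what
the round-trip tests assert. One motif-model field is deliberately relaxed
relative to real MEME output: a motif may carry zero sites (site
probability 0 is a supported edge case), in which case the writers emit a
one-hot consensus probability matrix.

What the generator does *not* emulate: MEME's EM fitting, its E-value
statistics, HTML output, and sequence-level composition biases. Passing
round trips therefore demonstrates that the parsers read the dialects'
structure correctly, not that any statistical property of real MEME output
is reproduced.

## Problem sizes and numerical choices

The test suite and acceptance script use 20 seeded generator
configurations (including 0-motif, 1-sequence, width-1, DNA/RNA/protein
edge cases), 1000 random logo columns, trees up to 200 tips, 100 random
trees for the serialization fixpoint, a 20-sequence / 37-occurrence figure
fixture and a 10,000-row filter table — sizes chosen so the whole suite
runs in well under a minute while still exercising every contract at
non-toy scale. Stack-height conservation and column normalization are
asserted at 1e-9; the small-sample correction's vanishing limit at
n = 10^6 at 1e-5 bits.

## Known limitations

* MAST/FIMO/TOMTOM outputs and MEME's HTML report are not parsed; MEME 4.x
  is rejected by design.
* The fixture writers target the subset of the dialects the parsers read;
  they are not a MEME-interoperable emitter.
* Relative-entropy (background-weighted) logos and difference logos are
  not implemented.
* Trees with a single tip cannot be drawn beside tracks (a one-row figure
  needs no tree), and the dataset generator skips the tree file for
  single-sequence runs.
* Figures are structurally deterministic (geometry, element counts) but
  not byte-identical across graphics library versions.
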