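# Helpers shared across the suite: deterministic fixtures built in code.

# A generated dataset written to a fresh temp dir; returns paths + truth.
makeDataset <- function(spec = motifSimSpec(), ...) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  files <- simulateMemeDataset(d, spec, ...)
  list(files = files, truth = attr(files, "truth"), dir = d)
}

# Deterministic occurrence table with exactly nOcc occurrences spread over
# nSeq sequences (round robin), all widths 5, protein.
makeOccurrenceTable <- function(nSeq = 20L, nOcc = 37L, width = 5L) {
  names <- sprintf("S%03d.1", seq_len(nSeq))
  lens <- 100L + 10L * (seq_len(nSeq) %% 7L)
  seqIdx <- rep(seq_len(nSeq), length.out = nOcc)
  hitNo <- stats::ave(seqIdx, seqIdx, FUN = seq_along)
  start <- 1L + (hitNo - 1L) * (width + 3L)
  data.frame(
    sequence_name = names[seqIdx],
    sequence_length = lens[seqIdx],
    motif_id = sprintf("motif_%d", 1L + (seq_len(nOcc) %% 3L)),
    start = start, end = start + width - 1L,
    strand = "none",
    p_value = signif(10^seq(-10, -3, length.out = nOcc), 3),
    site_sequence = strrep("A", width),
    left_flank = "", right_flank = "",
    stringsAsFactors = FALSE)
}

# Caterpillar newick over the given labels, added tip by tip:
# (((A,B),C),D); — leaf order equals construction order.
caterpillarNewick <- function(labels) {
  s <- sprintf("(%s,%s)", labels[1], labels[2])
  for (l in labels[-(1:2)]) s <- sprintf("(%s,%s)", s, l)
  paste0(s, ";")
}

# Balanced newick via recursive halving; leaf order equals `labels`.
balancedNewick <- function(labels) {
  build <- function(v) {
    if (length(v) == 1L) return(v)
    mid <- ceiling(length(v) / 2)
    sprintf("(%s,%s)", build(v[seq_len(mid)]), build(v[-seq_len(mid)]))
  }
  paste0(build(labels), ";")
}
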