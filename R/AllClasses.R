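#' @import methods
NULL

#' PositionProbabilityMatrix: per-column letter probabilities of a motif
#'
#' A K x W matrix of letter probabilities (rows = alphabet letters in fixed
#' order, columns = motif positions) together with the number of sites the
#' matrix was estimated from. This is the object sequence logos are computed
#' from.
#'
#' @slot alphabet Character vector of the K letters (row order of `probs`).
#' @slot probs Numeric K x W matrix; every column sums to 1.
#' @slot nSites Integer; number of site sequences behind the estimate.
#'
#' @seealso [sitesToPPM()], [informationContent()], [renderLogo()]
#' @export
setClass("PositionProbabilityMatrix",
  representation(alphabet = "character", probs = "matrix", nSites = "integer"))

setValidity("PositionProbabilityMatrix", function(object) {
  msg <- character(0)
  K <- length(object@alphabet)
  if (K < 2L) msg <- c(msg, "alphabet must have at least 2 letters")
  if (nrow(object@probs) != K)
    msg <- c(msg, "probs must have one row per alphabet letter")
  if (ncol(object@probs) < 1L) msg <- c(msg, "width must be >= 1")
  if (any(object@probs < 0)) msg <- c(msg, "probabilities must be >= 0")
  cs <- colSums(object@probs)
  if (length(cs) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, sprintf("column %d does not sum to 1",
                          which.max(abs(cs - 1))))
  if (length(object@nSites) != 1L || is.na(object@nSites) || object@nSites < 1L)
    msg <- c(msg, "nSites must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' SequenceLogo: information-content letter heights for a motif
#'
#' The per-column information content (bits) and letter stack heights derived
#' from a [PositionProbabilityMatrix-class], optionally with the
#' small-sample correction applied.
#'
#' @slot ppm The source `PositionProbabilityMatrix`.
#' @slot ic Numeric vector of per-column information content R_i in bits.
#' @slot heights Numeric K x W matrix of letter heights (p_ik * R_i).
#' @slot correction Logical; whether the small-sample correction was applied.
#'
#' @export
setClass("SequenceLogo",
  representation(ppm = "PositionProbabilityMatrix", ic = "numeric",
                 heights = "matrix", correction = "logical"))

setValidity("SequenceLogo", function(object) {
  msg <- character(0)
  W <- ncol(object@ppm@probs)
  K <- length(object@ppm@alphabet)
  if (length(object@ic) != W) msg <- c(msg, "ic length must equal ppm width")
  if (any(object@ic < -1e-12) || any(object@ic > log2(K) + 1e-9))
    msg <- c(msg, "ic must lie in [0, log2(K)]")
  if (!identical(dim(object@heights), dim(object@ppm@probs)))
    msg <- c(msg, "heights must have the ppm's dimensions")
  if (length(object@ic) &&
      any(abs(colSums(object@heights) - object@ic) > 1e-9))
    msg <- c(msg, "stack heights must sum to the column ic")
  if (length(msg)) msg else TRUE
})

#' MemeResult: one parsed MEME run
#'
#' Holds everything extracted from a MEME 5.x result file (either dialect):
#' run metadata, the training sequences, the motif models with their
#' position probability matrices, and the motif occurrences (contributing
#' sites) with 1-based inclusive coordinates. The XML dialect's optional
#' scanned-sites summary, when present, is kept in a separate slot and never
#' merged into the canonical occurrence set.
#'
#' @slot version MEME version string, e.g. `"5.4.1"`.
#' @slot alphabet One of `"DNA"`, `"RNA"`, `"PROTEIN"`.
#' @slot letters The alphabet's letter set.
#' @slot background Named numeric vector of background letter frequencies
#'   (sums to 1).
#' @slot commandLine The recorded MEME command line (may be empty).
#' @slot sequences data.frame of training sequences: `seq_id`, `name`,
#'   `length`, `weight`.
#' @slot motifs data.frame of motif models: `motif_id`, `name` (consensus),
#'   `alt`, `width`, `nsites`, `e_value`, `bayes_threshold`.
#' @slot ppms Named list (by `motif_id`) of
#'   [PositionProbabilityMatrix-class] objects; may be empty.
#' @slot occurrences data.frame of contributing sites (see
#'   [occurrenceTable()] for the columns).
#' @slot scannedSites data.frame of the scanned-sites summary
#'   (`sequence_name`, `motif_id`, `start`, `strand`, `p_value`); 0 rows
#'   when the input carries none.
#'
#' @seealso [parseMemeXML()], [parseMemeText()], [occurrenceTable()]
#' @export
setClass("MemeResult",
  representation(version = "character", alphabet = "character",
                 letters = "character", background = "numeric",
                 commandLine = "character", sequences = "data.frame",
                 motifs = "data.frame", ppms = "list",
                 occurrences = "data.frame", scannedSites = "data.frame"))

setValidity("MemeResult", function(object) {
  msg <- character(0)
  if (!object@alphabet %in% c("DNA", "RNA", "PROTEIN"))
    msg <- c(msg, "alphabet must be DNA, RNA or PROTEIN")
  if (length(object@background) &&
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background frequencies must sum to 1")
  if (anyDuplicated(object@sequences$seq_id))
    msg <- c(msg, "sequence ids must be unique")
  if (nrow(object@sequences) && any(object@sequences$length < 1L))
    msg <- c(msg, "sequence lengths must be >= 1")
  occ <- object@occurrences
  if (nrow(occ)) {
    if (!all(occ$sequence_name %in% object@sequences$name))
      msg <- c(msg, "occurrence references an unknown sequence name")
    if (!all(occ$motif_id %in% object@motifs$motif_id))
      msg <- c(msg, "occurrence references an unknown motif id")
    if (any(occ$start < 1L) || any(occ$end < occ$start) ||
        any(occ$end > occ$sequence_length))
      msg <- c(msg, "occurrence coordinates must satisfy 1 <= start <= end <= sequence_length")
    w <- object@motifs$width[match(occ$motif_id, object@motifs$motif_id)]
    if (any(occ$end - occ$start + 1L != w))
      msg <- c(msg, "occurrence span must equal the motif width")
    if (any(nchar(occ$site_sequence) != w))
      msg <- c(msg, "site sequence length must equal the motif width")
    siteLetters <- unique(strsplit(paste(occ$site_sequence, collapse = ""),
                                   "")[[1]])
    if (!all(siteLetters %in% object@letters))
      msg <- c(msg, "site sequences contain letters outside the alphabet")
    if (object@alphabet == "PROTEIN" && !all(occ$strand == "none"))
      msg <- c(msg, "protein occurrences must have strand 'none'")
    if (any(occ$p_value <= 0) || any(occ$p_value > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
  }
  for (id in names(object@ppms)) {
    w <- object@motifs$width[match(id, object@motifs$motif_id)]
    if (!is.na(w) && ncol(object@ppms[[id]]@probs) != w)
      msg <- c(msg, sprintf("ppm for %s has wrong width", id))
  }
  if (length(msg)) msg else TRUE
})

#' TrackLayout: resolved geometry of a motif-location figure
#'
#' One row (horizontal track) per sequence, one box per motif occurrence,
#' and a stable motif-to-color map. This object is the testable geometry
#' behind [renderLocations()]; it can be serialized with
#' [writeTrackLayoutJSON()].
#'
#' @slot rows data.frame: `sequence_name`, `sequence_length`, `y` (row index
#'   1..T, top to bottom).
#' @slot boxes data.frame: `row` (index into rows), `motif_id`, `start`,
#'   `end`, `strand`.
#' @slot xMax Maximum sequence length across rows (shared x-axis).
#' @slot colorMap Named character vector motif_id -> color; a pure function
#'   of the sorted motif-id set.
#'
#' @seealso [buildTracks()], [renderLocations()]
#' @export
setClass("TrackLayout",
  representation(rows = "data.frame", boxes = "data.frame",
                 xMax = "numeric", colorMap = "character"))

setValidity("TrackLayout", function(object) {
  msg <- character(0)
  if (!identical(object@rows$y, seq_len(nrow(object@rows))))
    msg <- c(msg, "row indices must be consecutive from 1")
  b <- object@boxes
  if (nrow(b)) {
    if (any(b$row < 1L) || any(b$row > nrow(object@rows)))
      msg <- c(msg, "box row index out of range")
    len <- object@rows$sequence_length[b$row]
    if (any(b$start < 1L) || any(b$end < b$start) || any(b$end > len))
      msg <- c(msg, "box [start, end] must lie within its row's sequence")
    if (!all(b$motif_id %in% names(object@colorMap)))
      msg <- c(msg, "every box motif must have a color")
  }
  if (length(msg)) msg else TRUE
})

#' MotifSimSpec: parameters of the synthetic MEME-run generator
#'
#' Describes a simulated ZOOPS-style motif discovery run: each motif plants
#' at most one site per sequence, with the given per-sequence probability.
#' The defaults mirror a typical protein family scan: 10 motifs of widths
#' 4-7 over 20 sequences.
#'
#' @slot seed Integer RNG seed; generation is deterministic given the spec.
#' @slot alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @slot nSequences Number of training sequences.
#' @slot lengthRange Integer length-2; sequence lengths sampled uniformly.
#' @slot nMotifs Number of motifs.
#' @slot widthRange Integer length-2; motif widths sampled uniformly.
#' @slot siteProb Per-sequence, per-motif probability of planting a site.
#' @slot consensusProb Probability that a site letter equals the motif's
#'   consensus letter at that column (the degenerate-consensus site model).
#' @slot pValueRange Planted site p-values are sampled log-uniformly in this
#'   range (then rounded to 3 significant digits, the precision the result
#'   files print).
#'
#' @seealso [motifSimSpec()], [simulateMotifData()]
#' @export
setClass("MotifSimSpec",
  representation(seed = "integer", alphabet = "character",
                 nSequences = "integer", lengthRange = "integer",
                 nMotifs = "integer", widthRange = "integer",
                 siteProb = "numeric", consensusProb = "numeric",
                 pValueRange = "numeric"))

setValidity("MotifSimSpec", function(object) {
  msg <- character(0)
  if (!object@alphabet %in% c("DNA", "RNA", "PROTEIN"))
    msg <- c(msg, "alphabet must be DNA, RNA or PROTEIN")
  if (object@nSequences < 1L) msg <- c(msg, "nSequences must be >= 1")
  if (object@nMotifs < 0L) msg <- c(msg, "nMotifs must be >= 0")
  if (object@widthRange[1] < 1L)
    msg <- c(msg, "motif widths must be >= 1")
  if (object@widthRange[2] > object@lengthRange[1])
    msg <- c(msg, "motif widths may not exceed the minimum sequence length")
  if (object@siteProb < 0 || object@siteProb > 1)
    msg <- c(msg, "siteProb must lie in [0, 1]")
  if (object@pValueRange[1] <= 0 || object@pValueRange[2] > 1)
    msg <- c(msg, "pValueRange must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' MotifGroundTruth: a simulated MEME run with known planted sites
#'
#' The generator's output: sequences, motif models and the planted
#' occurrences, plus the run metadata the file writers emit. Serves as the
#' oracle for all round-trip tests: `parseMemeXML(writeMemeXML(truth))`
#' must reproduce `occurrenceTable(truth)` exactly.
#'
#' @slot spec The [MotifSimSpec-class] that produced it.
#' @slot alphabet,letters,background,version,commandLine Run metadata, as in
#'   [MemeResult-class].
#' @slot sequences data.frame: `seq_id`, `name`, `length`, `weight`.
#' @slot motifs data.frame: `motif_id`, `name` (consensus), `alt`, `width`,
#'   `nsites`, `e_value`, `bayes_threshold`.
#' @slot occurrences data.frame of planted sites (occurrence columns).
#'
#' @seealso [simulateMotifData()], [writeMemeXML()], [writeMemeText()]
#' @export
setClass("MotifGroundTruth",
  representation(spec = "MotifSimSpec", alphabet = "character",
                 letters = "character", background = "numeric",
                 version = "character", commandLine = "character",
                 sequences = "data.frame", motifs = "data.frame",
                 occurrences = "data.frame"))

## ---- show methods -------------------------------------------------------

setMethod("show", "PositionProbabilityMatrix", function(object) {
  cat(sprintf("PositionProbabilityMatrix: %d letters x %d positions (n = %d sites)\n",
              length(object@alphabet), ncol(object@probs), object@nSites))
})

setMethod("show", "SequenceLogo", function(object) {
  cat(sprintf("SequenceLogo: %d columns, total IC %.2f bits (correction %s)\n",
              length(object@ic), sum(object@ic),
              if (object@correction) "on" else "off"))
})

setMethod("show", "MemeResult", function(object) {
  cat(sprintf("MemeResult (MEME %s, %s)\n", object@version, object@alphabet))
  cat(sprintf("  %d sequences, %d motifs, %d occurrences\n",
              nrow(object@sequences), nrow(object@motifs),
              nrow(object@occurrences)))
  if (nrow(object@scannedSites))
    cat(sprintf("  + scanned-sites summary with %d entries\n",
                nrow(object@scannedSites)))
})

setMethod("show", "TrackLayout", function(object) {
  cat(sprintf("TrackLayout: %d rows, %d boxes, x in [1, %d], %d motifs\n",
              nrow(object@rows), nrow(object@boxes), object@xMax,
              length(object@colorMap)))
})

setMethod("show", "MotifSimSpec", function(object) {
  cat(sprintf("MotifSimSpec: seed %d, %s, %d sequences (len %d-%d), %d motifs (w %d-%d), siteProb %.2f\n",
              object@seed, object@alphabet, object@nSequences,
              object@lengthRange[1], object@lengthRange[2], object@nMotifs,
              object@widthRange[1], object@widthRange[2], object@siteProb))
})

setMethod("show", "MotifGroundTruth", function(object) {
  cat(sprintf("MotifGroundTruth: %d sequences, %d motifs, %d planted occurrences (%s)\n",
              nrow(object@sequences), nrow(object@motifs),
              nrow(object@occurrences), object@alphabet))
})
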