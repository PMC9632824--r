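#' Accessors for motifscape objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x A motifscape object.
#' @param ... Passed to methods.
#' @return The corresponding component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("memeVersion", function(x) standardGeneric("memeVersion"))

#' @rdname accessors
#' @export
setGeneric("memeAlphabet", function(x) standardGeneric("memeAlphabet"))

#' @rdname accessors
#' @export
setGeneric("alphabetLetters", function(x) standardGeneric("alphabetLetters"))

#' @rdname accessors
#' @export
setGeneric("backgroundFrequencies",
           function(x) standardGeneric("backgroundFrequencies"))

#' @rdname accessors
#' @export
setGeneric("memeCommandLine", function(x) standardGeneric("memeCommandLine"))

#' @rdname accessors
#' @export
setGeneric("trainingSequences", function(x) standardGeneric("trainingSequences"))

#' @rdname accessors
#' @export
setGeneric("motifModels", function(x) standardGeneric("motifModels"))

#' @rdname accessors
#' @export
setGeneric("motifPPM", function(x, motifId) standardGeneric("motifPPM"))

#' @rdname accessors
#' @export
setGeneric("scannedSites", function(x) standardGeneric("scannedSites"))

#' Normalized motif-occurrence table
#'
#' One row per motif occurrence, deterministically ordered by
#' `sequence_name`, then `start`, then `motif_id`. Every row carries
#' `sequence_length`, so the table alone suffices for plotting.
#'
#' @param x A [MemeResult-class] or [MotifGroundTruth-class].
#' @return data.frame with columns `sequence_name`, `sequence_length`,
#'   `motif_id`, `start`, `end`, `strand`, `p_value`, `site_sequence`,
#'   `left_flank`, `right_flank`. Coordinates are 1-based inclusive.
#' @examples
#' truth <- simulateMotifData(motifSimSpec(seed = 1))
#' head(occurrenceTable(truth))
#' @export
setGeneric("occurrenceTable", function(x) standardGeneric("occurrenceTable"))

#' @rdname accessors
#' @export
setGeneric("ppmMatrix", function(x) standardGeneric("ppmMatrix"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("trackRows", function(x) standardGeneric("trackRows"))

#' @rdname accessors
#' @export
setGeneric("trackBoxes", function(x) standardGeneric("trackBoxes"))

#' @rdname accessors
#' @export
setGeneric("trackColorMap", function(x) standardGeneric("trackColorMap"))

## ---- methods ------------------------------------------------------------

#' @rdname accessors
setMethod("memeVersion", "MemeResult", function(x) x@version)
#' @rdname accessors
setMethod("memeAlphabet", "MemeResult", function(x) x@alphabet)
#' @rdname accessors
setMethod("alphabetLetters", "MemeResult", function(x) x@letters)
#' @rdname accessors
setMethod("backgroundFrequencies", "MemeResult", function(x) x@background)
#' @rdname accessors
setMethod("memeCommandLine", "MemeResult", function(x) x@commandLine)
#' @rdname accessors
setMethod("trainingSequences", "MemeResult", function(x) x@sequences)
#' @rdname accessors
setMethod("motifModels", "MemeResult", function(x) x@motifs)
#' @rdname accessors
setMethod("scannedSites", "MemeResult", function(x) x@scannedSites)

#' @rdname accessors
setMethod("motifPPM", "MemeResult", function(x, motifId) {
  if (!motifId %in% x@motifs$motif_id)
    .usageError("unknown motif id: ", motifId)
  x@ppms[[motifId]]
})

setMethod("occurrenceTable", "MemeResult",
          function(x) .orderOccurrences(x@occurrences))

#' @rdname accessors
setMethod("memeAlphabet", "MotifGroundTruth", function(x) x@alphabet)
#' @rdname accessors
setMethod("alphabetLetters", "MotifGroundTruth", function(x) x@letters)
#' @rdname accessors
setMethod("backgroundFrequencies", "MotifGroundTruth", function(x) x@background)
#' @rdname accessors
setMethod("trainingSequences", "MotifGroundTruth", function(x) x@sequences)
#' @rdname accessors
setMethod("motifModels", "MotifGroundTruth", function(x) x@motifs)

setMethod("occurrenceTable", "MotifGroundTruth",
          function(x) .orderOccurrences(x@occurrences))

#' @rdname accessors
setMethod("ppmMatrix", "PositionProbabilityMatrix", function(x) x@probs)
#' @rdname accessors
setMethod("nSites", "PositionProbabilityMatrix", function(x) x@nSites)
#' @rdname accessors
setMethod("alphabetLetters", "PositionProbabilityMatrix",
          function(x) x@alphabet)

#' @rdname accessors
setMethod("trackRows", "TrackLayout", function(x) x@rows)
#' @rdname accessors
setMethod("trackBoxes", "TrackLayout", function(x) x@boxes)
#' @rdname accessors
setMethod("trackColorMap", "TrackLayout", function(x) x@colorMap)
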