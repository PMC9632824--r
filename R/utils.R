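## Shared constants and low-level helpers.

.ALPHABETS <- list(
  DNA     = c("A", "C", "G", "T"),
  RNA     = c("A", "C", "G", "U"),
  PROTEIN = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

.OCC_COLUMNS <- c("sequence_name", "sequence_length", "motif_id",
                  "start", "end", "strand", "p_value",
                  "site_sequence", "left_flank", "right_flank")

#' Letters of a named alphabet
#'
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"` (case-insensitive), or a
#'   character vector of single letters taken verbatim.
#' @return Character vector of letters.
#' @keywords internal
.alphabetLetters <- function(alphabet) {
  if (length(alphabet) == 1L && toupper(alphabet) %in% names(.ALPHABETS)) {
    return(.ALPHABETS[[toupper(alphabet)]])
  }
  if (all(nchar(alphabet) == 1L) && length(alphabet) > 1L) {
    return(alphabet)
  }
  stop("unknown alphabet: ", paste(alphabet, collapse = ""), call. = FALSE)
}

## Classify a letter set as DNA / RNA / PROTEIN (exact set match).
.alphabetName <- function(letters) {
  for (nm in names(.ALPHABETS)) {
    if (setequal(letters, .ALPHABETS[[nm]])) return(nm)
  }
  stop("letter set matches no supported alphabet: ",
       paste(sort(letters), collapse = ""), call. = FALSE)
}

## Numeric parse tolerant of the unicode minus some reports print.
.parseNum <- function(x) {
  suppressWarnings(as.numeric(gsub("−", "-", x)))
}

## Condition constructors backing the exit-code contract
## (0 ok, 1 usage, 2 format/I-O).
.formatError <- function(...) {
  stop(errorCondition(paste0(...), class = c("motifscapeFormatError", "error")))
}

.ioError <- function(...) {
  stop(errorCondition(paste0(...), class = c("motifscapeIOError", "error")))
}

.usageError <- function(...) {
  stop(errorCondition(paste0(...), class = c("motifscapeUsageError", "error")))
}

## 0-row occurrence frame with the full column set.
.emptyOccurrences <- function() {
  data.frame(sequence_name = character(0), sequence_length = integer(0),
             motif_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), p_value = numeric(0),
             site_sequence = character(0), left_flank = character(0),
             right_flank = character(0), stringsAsFactors = FALSE)
}

## Canonical occurrence ordering: sequence_name, start, then motif_id.
.orderOccurrences <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$sequence_name, df$start, df$motif_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Full-precision numeric -> string (round-trip safe).
.numToChr <- function(x) sprintf("%.17g", x)

## column names used in non-standard evaluation inside ggplot2 aes()
utils::globalVariables(c("x", "y", "group", "letter", "xmin", "xmax",
                         "ymin", "ymax", "motif_id", "label", "xend",
                         "yend", "sequence_length", "start", "end",
                         "px", "py", ".anno"))
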