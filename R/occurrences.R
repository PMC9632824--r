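## Filter surface and TSV round trip for the normalized occurrence table.

#' Filter a motif-occurrence table
#'
#' Applies the conjunction of the supplied predicates; absent predicates are
#' no-ops and the original row order is preserved. Motif-level thresholds
#' (`maxE`, `maxBayes`) are looked up in the motif models, so they require
#' either a [MemeResult-class] as `x` or a `motifStats` table.
#'
#' @param x An occurrence table (see [occurrenceTable()]) or a
#'   [MemeResult-class].
#' @param motifIds Optional character vector of motif ids to keep. Ids not
#'   present in the table raise a warning, not an error (they may
#'   legitimately select nothing).
#' @param maxP Optional site p-value cutoff in (0, 1]; rows with
#'   `p_value <= maxP` survive.
#' @param maxE Optional motif E-value cutoff (`e_value <= maxE`).
#' @param maxBayes Optional motif Bayes-threshold cutoff
#'   (`bayes_threshold <= maxBayes`).
#' @param motifStats Optional data.frame with `motif_id`, `e_value`,
#'   `bayes_threshold` (as from [motifModels()]); required for
#'   `maxE`/`maxBayes` when `x` is a plain table without those columns.
#' @return The filtered table, same columns, original order.
#' @examples
#' truth <- simulateMotifData(motifSimSpec(seed = 1))
#' tab <- occurrenceTable(truth)
#' nrow(filterOccurrences(tab, maxP = 1e-6))
#' @export
filterOccurrences <- function(x, motifIds = NULL, maxP = NULL, maxE = NULL,
                              maxBayes = NULL, motifStats = NULL) {
  if (is(x, "MemeResult")) {
    if (is.null(motifStats)) motifStats <- motifModels(x)
    x <- occurrenceTable(x)
  }
  if (!is.data.frame(x) || !all(c("motif_id", "p_value") %in% names(x)))
    .usageError("x must be an occurrence table with motif_id and p_value columns")
  keep <- rep(TRUE, nrow(x))
  if (!is.null(maxP)) {
    if (!is.numeric(maxP) || length(maxP) != 1L || maxP <= 0 || maxP > 1)
      .usageError("maxP must be a single value in (0, 1]")
    keep <- keep & x$p_value <= maxP
  }
  if (!is.null(motifIds)) {
    unknown <- setdiff(motifIds, unique(x$motif_id))
    if (length(unknown))
      warning("motif id(s) not present in the table: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    keep <- keep & x$motif_id %in% motifIds
  }
  if (!is.null(maxE) || !is.null(maxBayes)) {
    stats <- motifStats
    if (is.null(stats)) {
      if (all(c("e_value", "bayes_threshold") %in% names(x))) {
        stats <- unique(x[, c("motif_id", "e_value", "bayes_threshold")])
      } else {
        .usageError("maxE/maxBayes need motif-level fields: pass a MemeResult or motifStats")
      }
    }
    ev <- stats$e_value[match(x$motif_id, stats$motif_id)]
    bt <- stats$bayes_threshold[match(x$motif_id, stats$motif_id)]
    if (!is.null(maxE)) keep <- keep & !is.na(ev) & ev <= maxE
    if (!is.null(maxBayes)) keep <- keep & !is.na(bt) & bt <= maxBayes
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an occurrence table as TSV
#'
#' Tab-separated, header row, UTF-8, one line per occurrence. P-values are
#' written with full precision (`%.17g`) so the round trip is lossless.
#'
#' @param table An occurrence table.
#' @param path File path.
#' @return `path` invisibly (writer); the table (reader).
#' @examples
#' truth <- simulateMotifData(motifSimSpec(seed = 2, nSequences = 5))
#' f <- tempfile(fileext = ".tsv")
#' writeOccurrenceTSV(occurrenceTable(truth), f)
#' identical(readOccurrenceTSV(f), occurrenceTable(truth))
#' @export
writeOccurrenceTSV <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  if ("p_value" %in% names(out)) out$p_value <- .numToChr(out$p_value)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e)
    .ioError("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  invisible(path)
}

#' @rdname writeOccurrenceTSV
#' @export
readOccurrenceTSV <- function(path) {
  if (!file.exists(path)) .ioError("file not found: ", path)
  classes <- c(sequence_name = "character", sequence_length = "integer",
               motif_id = "character", start = "integer", end = "integer",
               strand = "character", p_value = "numeric",
               site_sequence = "character", left_flank = "character",
               right_flank = "character")
  ## read everything as character first: a column of bare "T"/"F" site
  ## letters must not be type-converted to logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = character(0))
  for (cn in intersect(names(classes), names(df))) {
    df[[cn]] <- switch(classes[[cn]],
                       character = as.character(df[[cn]]),
                       integer = as.integer(df[[cn]]),
                       numeric = as.numeric(df[[cn]]))
  }
  df
}
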