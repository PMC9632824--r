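## Writers emitting the MEME 5.x XML and plain-text dialects from a
## MotifGroundTruth. They target exactly the dialect subset the parsers
## read; fields the parsers ignore carry constant placeholders. The XML
## writes 0-based site offsets, the text writes 1-based starts, so a
## round trip exercises the coordinate conversion.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.strandXML <- function(s) c("+" = "plus", "-" = "minus", "none" = "none")[s]

#' Write a ground truth as a MEME 5.x XML results file
#'
#' Contributing-site positions are emitted as 0-based offsets (the XML
#' dialect's convention); a scanned-sites summary mirroring the planted
#' sites is included so the optional summary path is exercised.
#'
#' @param truth A [MotifGroundTruth-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [parseMemeXML()], [writeMemeText()]
#' @export
writeMemeXML <- function(truth, path) {
  stopifnot(is(truth, "MotifGroundTruth"))
  seqs <- truth@sequences
  letters <- truth@letters
  alphName <- c(DNA = "DNA", RNA = "RNA", PROTEIN = "Protein")[truth@alphabet]
  like <- tolower(alphName)
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)

  add('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>')
  add('<!-- Document definition -->')
  add(sprintf('<MEME version="%s" release="Sat Aug 21 19:23:23 2021 -0700">',
              truth@version))
  add(sprintf('<training_set primary_sequences="sequences.fa" primary_count="%d" primary_positions="%d" control_sequences="--none--" control_count="0" control_positions="0">',
              nrow(seqs), sum(seqs$length)))
  add(sprintf('<alphabet name="%s" like="%s">', alphName, like))
  for (l in letters)
    add(sprintf('<letter id="%s" symbol="%s" name="%s"/>', l, l, l))
  add('</alphabet>')
  for (i in seq_len(nrow(seqs)))
    add(sprintf('<sequence id="%s" name="%s" length="%d" weight="%.6f"/>',
                seqs$seq_id[i], .xmlEscape(seqs$name[i]), seqs$length[i],
                seqs$weight[i]))
  add('<letter_frequencies>')
  add('<alphabet_array>')
  for (l in letters)
    add(sprintf('<value letter_id="%s">%.6f</value>', l,
                truth@background[[l]]))
  add('</alphabet_array>')
  add('</letter_frequencies>')
  add('</training_set>')
  add('<model>')
  add(sprintf('<command_line>%s</command_line>', .xmlEscape(truth@commandLine)))
  add('<host>localhost</host>')
  add('<type>zoops</type>')
  add('<nmotifs>', nrow(truth@motifs), '</nmotifs>')
  add('<object_function>E-value of product of p-values</object_function>')
  add(sprintf('<background_frequencies source="--sequences--" order="0">'))
  add('<alphabet_array>')
  for (l in letters)
    add(sprintf('<value letter_id="%s">%.6f</value>', l,
                truth@background[[l]]))
  add('</alphabet_array>')
  add('</background_frequencies>')
  add('</model>')
  add('<motifs>')
  nameById <- stats::setNames(seqs$seq_id, seqs$name)
  occAll <- truth@occurrences
  for (i in seq_len(nrow(truth@motifs))) {
    m <- truth@motifs[i, ]
    add(sprintf('<motif id="%s" name="%s" alt="%s" width="%d" sites="%d" ic="10.0" re="10.0" llr="100" p_value="1.0e-100" e_value="%.1e" bayes_threshold="%.5f" elapsed_time="1.0">',
                m$motif_id, m$name, m$alt, m$width, m$nsites, m$e_value,
                m$bayes_threshold))
    probs <- .truthPPMMatrix(truth, m$motif_id)
    add('<probabilities>')
    add('<alphabet_matrix>')
    for (j in seq_len(ncol(probs))) {
      add('<alphabet_array>')
      for (l in letters)
        add(sprintf('<value letter_id="%s">%.6f</value>', l, probs[l, j]))
      add('</alphabet_array>')
    }
    add('</alphabet_matrix>')
    add('</probabilities>')
    add(sprintf('<regular_expression>%s</regular_expression>', m$name))
    add('<contributing_sites>')
    occ <- occAll[occAll$motif_id == m$motif_id, , drop = FALSE]
    for (k in seq_len(nrow(occ))) {
      o <- occ[k, ]
      add(sprintf('<contributing_site sequence_id="%s" position="%d" strand="%s" pvalue="%.2e">',
                  nameById[[o$sequence_name]], o$start - 1L,
                  .strandXML(o$strand), o$p_value))
      add(sprintf('<left_flank>%s</left_flank>', o$left_flank))
      refs <- paste(sprintf('<letter_ref letter_id="%s"/>',
                            strsplit(o$site_sequence, "")[[1]]),
                    collapse = "")
      add('<site>', refs, '</site>')
      add(sprintf('<right_flank>%s</right_flank>', o$right_flank))
      add('</contributing_site>')
    }
    add('</contributing_sites>')
    add('</motif>')
  }
  add('</motifs>')
  add('<scanned_sites_summary p_thresh="0.0001">')
  for (i in seq_len(nrow(seqs))) {
    occ <- occAll[occAll$sequence_name == seqs$name[i], , drop = FALSE]
    add(sprintf('<scanned_sites sequence_id="%s" pvalue="1.0e-10" num_sites="%d">',
                seqs$seq_id[i], nrow(occ)))
    for (k in seq_len(nrow(occ))) {
      o <- occ[k, ]
      add(sprintf('<scanned_site motif_id="%s" strand="%s" position="%d" pvalue="%.2e"/>',
                  o$motif_id, .strandXML(o$strand), o$start - 1L, o$p_value))
    }
    add('</scanned_sites>')
  }
  add('</scanned_sites_summary>')
  add('</MEME>')
  con <- tryCatch(file(path, "w"), error = function(e)
    .ioError("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(unlist(L), con)
  invisible(path)
}

.rule <- strrep("*", 80)
.dashes <- strrep("-", 80)

#' Write a ground truth as a MEME 5.x plain-text results file
#'
#' Emits the text blocks the text parser reads: the version header, the
#' TRAINING SET table, the background frequency line, and per motif the
#' `MOTIF ... MEME-k` header, the sites-sorted-by-p-value table (1-based
#' starts, with a Strand column for nucleotide alphabets), the
#' position-specific scoring matrix block (carrying the Bayes threshold on
#' its `log-odds matrix:` line) and the letter-probability matrix block.
#'
#' @param truth A [MotifGroundTruth-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [parseMemeText()], [writeMemeXML()]
#' @export
writeMemeText <- function(truth, path) {
  stopifnot(is(truth, "MotifGroundTruth"))
  seqs <- truth@sequences
  letters <- truth@letters
  K <- length(letters)
  nucleotide <- truth@alphabet %in% c("DNA", "RNA")
  L <- character(0)
  add <- function(...) L[[length(L) + 1L]] <<- paste0(...)

  add(.rule)
  add("MEME - Motif discovery tool")
  add(.rule)
  add(sprintf("MEME version %s (Release date: Sat Aug 21 19:23:23 2021 -0700)",
              truth@version))
  add("")
  add("For further information on how to interpret these results please access https://meme-suite.org/meme.")
  add("")
  add(.rule)
  add("TRAINING SET")
  add(.rule)
  add("PRIMARY SEQUENCES= sequences.fa")
  add("CONTROL SEQUENCES= --none--")
  add(sprintf("ALPHABET= %s", paste(letters, collapse = "")))
  if (nucleotide) add("STRANDS: + -")
  add("Sequence name            Weight Length  Sequence name            Weight Length")
  add("-------------            ------ ------  -------------            ------ ------")
  entries <- sprintf("%-24s %6.4f %6d", seqs$name, seqs$weight, seqs$length)
  for (i in seq(1, length(entries), by = 2)) {
    if (i + 1 <= length(entries))
      add(entries[i], "  ", entries[i + 1])
    else add(entries[i])
  }
  add(.rule)
  add("COMMAND LINE SUMMARY")
  add(.rule)
  add("This information can also be useful in the event you wish to report a")
  add("problem with the MEME software.")
  add("")
  add(sprintf("command: %s", truth@commandLine))
  add("")
  add(sprintf("model:  mod=         zoops    nmotifs=        %2d    evt=           inf",
              nrow(truth@motifs)))
  add("")
  add("Background letter frequencies (from file `sequences.fa'):")
  bg <- sprintf("%s %.5f", letters, truth@background)
  for (i in seq(1, K, by = 9))
    add(paste(bg[i:min(i + 8, K)], collapse = " "))
  add(.rule)

  occAll <- truth@occurrences
  lenByName <- stats::setNames(seqs$length, seqs$name)
  for (i in seq_len(nrow(truth@motifs))) {
    m <- truth@motifs[i, ]
    add("")
    add(.rule)
    add(sprintf("MOTIF %s %s\twidth =  %2d  sites =  %2d  llr = %d  E-value = %.1e",
                m$name, m$alt, m$width, m$nsites, 100L + i, m$e_value))
    add(.rule)
    occ <- occAll[occAll$motif_id == m$motif_id, , drop = FALSE]
    add(sprintf("\tMotif %s %s sites sorted by position p-value", m$name, m$alt))
    add(.dashes)
    if (nucleotide) {
      add("Sequence name            Strand  Start   P-value                    Site")
      add("-------------            ------  ----- ---------            --------------")
    } else {
      add("Sequence name            Start   P-value                    Site")
      add("-------------            ----- ---------            --------------")
    }
    ord <- order(occ$p_value, occ$sequence_name)
    for (k in ord) {
      o <- occ[k, ]
      siteCols <- c(if (nzchar(o$left_flank)) o$left_flank,
                    o$site_sequence,
                    if (nzchar(o$right_flank)) o$right_flank)
      if (nucleotide) {
        add(sprintf("%-24s %6s %6d  %8.2e %s",
                    o$sequence_name, o$strand, o$start, o$p_value,
                    paste(siteCols, collapse = " ")))
      } else {
        add(sprintf("%-24s %5d  %8.2e %s",
                    o$sequence_name, o$start, o$p_value,
                    paste(siteCols, collapse = " ")))
      }
    }
    add(.dashes)
    add("")
    probs <- .truthPPMMatrix(truth, m$motif_id)
    add(sprintf("\tMotif %s %s position-specific scoring matrix", m$name, m$alt))
    add(.dashes)
    add(sprintf("log-odds matrix: alength= %d w= %d n= %d bayes= %.5f E= %.1e",
                K, m$width, sum(lenByName) , m$bayes_threshold, m$e_value))
    for (j in seq_len(ncol(probs))) {
      lo <- ifelse(probs[, j] > 0,
                   round(100 * log2(pmax(probs[, j], 1e-6) /
                                    truth@background[letters])),
                   -999L)
      add(paste(sprintf("%6d", lo), collapse = " "))
    }
    add(.dashes)
    add("")
    add(sprintf("\tMotif %s %s position-specific probability matrix", m$name, m$alt))
    add(.dashes)
    add(sprintf("letter-probability matrix: alength= %d w= %d nsites= %d E= %.1e",
                K, m$width, m$nsites, m$e_value))
    for (j in seq_len(ncol(probs)))
      add(paste(sprintf("%9.6f", probs[, j]), collapse = " "))
    add(.dashes)
    add("")
  }
  add(.rule)
  add("SUMMARY OF MOTIFS")
  add(.rule)
  add("")
  add(sprintf("Stopped because requested number of motifs (%d) found.",
              nrow(truth@motifs)))
  add(.rule)
  con <- tryCatch(file(path, "w"), error = function(e)
    .ioError("cannot write ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(unlist(L), con)
  invisible(path)
}
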