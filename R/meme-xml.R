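## Parser for the MEME 5.x XML results dialect.

.STRAND_FROM_XML <- c(plus = "+", minus = "-", none = "none")

#' Parse a MEME XML results file
#'
#' Reads the `<MEME>` document written by MEME 5.x: training set (sequence
#' ids, names, lengths, weights, alphabet, letter frequencies), model
#' metadata, motif models with their position probability matrices, the
#' contributing sites (the canonical occurrence source: they carry
#' p-values, flanks and the site letters), and — when present — the
#' scanned-sites summary, kept in its own slot and never merged into the
#' occurrences.
#'
#' The XML dialect stores each contributing site's position as a 0-based
#' offset; it is converted to the package's 1-based inclusive convention
#' (`start = offset + 1`, `end = start + width - 1`), the coordinates a
#' biologist reads in the text report.
#'
#' @param path Path to a `meme.xml` file.
#' @return A [MemeResult-class].
#' @examples
#' files <- simulateMemeDataset(file.path(tempdir(), "xdemo"),
#'                              motifSimSpec(seed = 5, nSequences = 4))
#' parseMemeXML(files[["xml"]])
#' @export
parseMemeXML <- function(path) {
  if (!file.exists(path)) .ioError("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    .formatError("not well-formed XML (", path, "): ", conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "MEME")
    .formatError("not a MEME results document: root element is <",
                 xml2::xml_name(root), ">, expected <MEME>")
  version <- xml2::xml_attr(root, "version")
  if (is.na(version) || !grepl("^5(\\.|$)", version))
    .formatError("unsupported MEME dialect: found version ",
                 if (is.na(version)) "<missing>" else version,
                 ", only 5.x is supported")

  ts <- xml2::xml_find_first(root, "./training_set")
  if (inherits(ts, "xml_missing"))
    .formatError("MEME document is missing the <training_set> element")
  motifsNode <- xml2::xml_find_first(root, "./motifs")
  if (inherits(motifsNode, "xml_missing"))
    .formatError("MEME document is missing the <motifs> element")

  alphaNode <- xml2::xml_find_first(ts, "./alphabet")
  if (inherits(alphaNode, "xml_missing"))
    .formatError("MEME document is missing the <alphabet> element")
  letterNodes <- xml2::xml_find_all(alphaNode, "./letter")
  allLetters <- xml2::xml_attr(letterNodes, "symbol")
  alphaName <- toupper(xml2::xml_attr(alphaNode, "name"))
  alphabet <- if (!is.na(alphaName) && alphaName %in% names(.ALPHABETS)) {
    alphaName
  } else {
    ## no usable name attribute: classify by the core (non-ambiguity)
    ## letter set, trying each supported alphabet
    hit <- Filter(function(nm) all(.ALPHABETS[[nm]] %in% allLetters) &&
                    !("U" %in% allLetters && nm == "DNA"),
                  c("DNA", "RNA", "PROTEIN"))
    if (length(hit) == 0L)
      .formatError("cannot classify the alphabet letter set: ",
                   paste(allLetters, collapse = ""))
    hit[[length(hit)]]
  }
  letters <- .ALPHABETS[[alphabet]]
  idAttr <- xml2::xml_attr(letterNodes, "id")
  letterById <- stats::setNames(xml2::xml_attr(letterNodes, "symbol"), idAttr)

  seqNodes <- xml2::xml_find_all(ts, "./sequence")
  sequences <- data.frame(
    seq_id = xml2::xml_attr(seqNodes, "id"),
    name = xml2::xml_attr(seqNodes, "name"),
    length = as.integer(xml2::xml_attr(seqNodes, "length")),
    weight = .parseNum(xml2::xml_attr(seqNodes, "weight")),
    stringsAsFactors = FALSE)

  bgNodes <- xml2::xml_find_all(
    root, "./model/background_frequencies/alphabet_array/value")
  if (length(bgNodes) == 0L)
    bgNodes <- xml2::xml_find_all(ts, "./letter_frequencies/alphabet_array/value")
  background <- .parseNum(xml2::xml_text(bgNodes))
  names(background) <- unname(letterById[xml2::xml_attr(bgNodes, "letter_id")])
  background <- background[letters]

  cmd <- xml2::xml_text(xml2::xml_find_first(root, "./model/command_line"))
  if (is.na(cmd)) cmd <- ""

  nameById <- stats::setNames(sequences$name, sequences$seq_id)
  lenById <- stats::setNames(sequences$length, sequences$seq_id)

  motifNodes <- xml2::xml_find_all(motifsNode, "./motif")
  motifs <- data.frame(
    motif_id = xml2::xml_attr(motifNodes, "id"),
    name = xml2::xml_attr(motifNodes, "name"),
    alt = xml2::xml_attr(motifNodes, "alt"),
    width = as.integer(xml2::xml_attr(motifNodes, "width")),
    nsites = as.integer(xml2::xml_attr(motifNodes, "sites")),
    e_value = .parseNum(xml2::xml_attr(motifNodes, "e_value")),
    bayes_threshold = .parseNum(xml2::xml_attr(motifNodes, "bayes_threshold")),
    stringsAsFactors = FALSE)

  ppms <- list()
  occList <- list()
  for (i in seq_along(motifNodes)) {
    node <- motifNodes[[i]]
    mid <- motifs$motif_id[i]
    width <- motifs$width[i]
    cols <- xml2::xml_find_all(
      node, "./probabilities/alphabet_matrix/alphabet_array")
    if (length(cols)) {
      probs <- vapply(cols, function(col) {
        vals <- xml2::xml_find_all(col, "./value")
        v <- .parseNum(xml2::xml_text(vals))
        names(v) <- unname(letterById[xml2::xml_attr(vals, "letter_id")])
        v[letters]
      }, numeric(length(letters)))
      probs <- matrix(probs, nrow = length(letters),
                      dimnames = list(letters, NULL))
      probs <- sweep(probs, 2, colSums(probs), "/")  # undo print rounding
      ppms[[mid]] <- new("PositionProbabilityMatrix", alphabet = letters,
                         probs = probs,
                         nSites = max(1L, motifs$nsites[i]))
    }
    siteNodes <- xml2::xml_find_all(node, "./contributing_sites/contributing_site")
    if (length(siteNodes)) {
      sid <- xml2::xml_attr(siteNodes, "sequence_id")
      offset <- as.integer(xml2::xml_attr(siteNodes, "position"))
      strand <- .STRAND_FROM_XML[xml2::xml_attr(siteNodes, "strand")]
      pval <- .parseNum(xml2::xml_attr(siteNodes, "pvalue"))
      site <- vapply(siteNodes, function(s) {
        refs <- xml2::xml_find_all(s, "./site/letter_ref")
        paste(unname(letterById[xml2::xml_attr(refs, "letter_id")]),
              collapse = "")
      }, character(1))
      lf <- vapply(siteNodes, function(s)
        xml2::xml_text(xml2::xml_find_first(s, "./left_flank")), character(1))
      rf <- vapply(siteNodes, function(s)
        xml2::xml_text(xml2::xml_find_first(s, "./right_flank")), character(1))
      occList[[mid]] <- data.frame(
        sequence_name = unname(nameById[sid]),
        sequence_length = unname(lenById[sid]),
        motif_id = mid,
        start = offset + 1L, end = offset + width,
        strand = unname(strand), p_value = pval,
        site_sequence = site,
        left_flank = ifelse(is.na(lf), "", lf),
        right_flank = ifelse(is.na(rf), "", rf),
        stringsAsFactors = FALSE)
    }
  }
  occurrences <- if (length(occList)) do.call(rbind, occList)
                 else .emptyOccurrences()

  ssNodes <- xml2::xml_find_all(root, "./scanned_sites_summary/scanned_sites")
  scanned <- .emptyScannedSites()
  if (length(ssNodes)) {
    rows <- lapply(ssNodes, function(s) {
      hits <- xml2::xml_find_all(s, "./scanned_site")
      if (length(hits) == 0L) return(NULL)
      data.frame(
        sequence_name = unname(nameById[xml2::xml_attr(s, "sequence_id")]),
        motif_id = xml2::xml_attr(hits, "motif_id"),
        start = as.integer(xml2::xml_attr(hits, "position")) + 1L,
        strand = unname(.STRAND_FROM_XML[xml2::xml_attr(hits, "strand")]),
        p_value = .parseNum(xml2::xml_attr(hits, "pvalue")),
        stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) scanned <- do.call(rbind, rows)
  }

  res <- new("MemeResult", version = version, alphabet = alphabet,
             letters = letters, background = background, commandLine = cmd,
             sequences = sequences, motifs = motifs, ppms = ppms,
             occurrences = .orderOccurrences(occurrences),
             scannedSites = scanned)
  validObject(res)
  res
}

.emptyScannedSites <- function() {
  data.frame(sequence_name = character(0), motif_id = character(0),
             start = integer(0), strand = character(0),
             p_value = numeric(0), stringsAsFactors = FALSE)
}
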