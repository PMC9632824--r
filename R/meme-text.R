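## Parser for the MEME 5.x plain-text results dialect.

#' Parse a MEME plain-text results file
#'
#' Reads the `meme.txt` report written by MEME 5.x: the `MEME version 5...`
#' header, the TRAINING SET table (names, weights, lengths, alphabet), the
#' background letter frequencies, and for every motif the
#' `MOTIF <consensus> MEME-k` header (width, sites, E-value), the
#' "sites sorted by position p-value" table (sequence name, optional
#' strand, 1-based start, p-value, flanks and site string), the Bayes
#' threshold from the `log-odds matrix:` line, and the
#' `letter-probability matrix:` block.
#'
#' Text coordinates are already 1-based inclusive and are kept as printed.
#'
#' @param path Path to a `meme.txt` file.
#' @return A [MemeResult-class].
#' @examples
#' files <- simulateMemeDataset(file.path(tempdir(), "tdemo"),
#'                              motifSimSpec(seed = 5, nSequences = 4))
#' parseMemeText(files[["txt"]])
#' @export
parseMemeText <- function(path) {
  if (!file.exists(path)) .ioError("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("−", "-", lines)

  vline <- grep("^MEME version ", lines, value = TRUE)
  if (length(vline) == 0L)
    .formatError("no 'MEME version' header found in ", path,
                 "; not a MEME text results file")
  version <- sub("^MEME version (\\S+).*$", "\\1", vline[1])
  if (!grepl("^5(\\.|$)", version))
    .formatError("unsupported MEME dialect: found version ", version,
                 ", only 5.x is supported")

  aline <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(aline) == 0L)
    .formatError("missing ALPHABET= line in training set section")
  letters <- strsplit(trimws(sub("^ALPHABET=\\s*", "", aline[1])), "")[[1]]
  alphabet <- .alphabetName(letters)
  letters <- .ALPHABETS[[alphabet]]
  K <- length(letters)

  ## training set table: rows of (name weight length) groups, two per line
  hdr <- grep("^Sequence name\\s+Weight\\s+Length", lines)
  if (length(hdr) == 0L)
    .formatError("missing training-set sequence table")
  i <- hdr[1] + 2L
  names_ <- character(0); weights <- numeric(0); lens <- integer(0)
  while (i <= length(lines) && !grepl("^\\*{10,}", lines[i]) &&
         nzchar(trimws(lines[i]))) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) %% 3L != 0L)
      .formatError("malformed training-set row: ", lines[i])
    for (g in seq(1, length(tok), by = 3)) {
      names_ <- c(names_, tok[g])
      weights <- c(weights, .parseNum(tok[g + 1]))
      lens <- c(lens, as.integer(tok[g + 2]))
    }
    i <- i + 1L
  }
  sequences <- data.frame(
    seq_id = sprintf("sequence_%d", seq_along(names_) - 1L),
    name = names_, length = lens, weight = weights,
    stringsAsFactors = FALSE)
  lenByName <- stats::setNames(lens, names_)

  cmdLine <- grep("^command: ", lines, value = TRUE)
  cmd <- if (length(cmdLine)) sub("^command: ", "", cmdLine[1]) else ""

  background <- stats::setNames(rep(NA_real_, K), letters)
  bgAt <- grep("^Background letter frequencies", lines)
  if (length(bgAt)) {
    j <- bgAt[1] + 1L
    pairs <- character(0)
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           !grepl("^\\*{10,}", lines[j])) {
      pairs <- c(pairs, strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(pairs) %% 2L == 0L) {
      ls <- pairs[seq(1, length(pairs), 2)]
      vs <- .parseNum(pairs[seq(2, length(pairs), 2)])
      background[ls[ls %in% letters]] <- vs[ls %in% letters]
    }
  }
  if (anyNA(background)) background <- stats::setNames(rep(1 / K, K), letters)
  background <- background / sum(background)

  ## motif headers
  motifAt <- grep("^MOTIF\\s+\\S+\\s+MEME-\\d+\\s", lines)
  motifs <- data.frame(motif_id = character(0), name = character(0),
                       alt = character(0), width = integer(0),
                       nsites = integer(0), e_value = numeric(0),
                       bayes_threshold = numeric(0), stringsAsFactors = FALSE)
  ppms <- list()
  occ <- .emptyOccurrences()
  for (at in motifAt) {
    h <- lines[at]
    rx <- "^MOTIF\\s+(\\S+)\\s+MEME-(\\d+)\\s+width\\s*=\\s*(\\d+)\\s+sites\\s*=\\s*(\\d+).*E-value\\s*=\\s*(\\S+)"
    if (!grepl(rx, h)) .formatError("malformed MOTIF header: ", h)
    name <- sub(rx, "\\1", h)
    k <- as.integer(sub(rx, "\\2", h))
    width <- as.integer(sub(rx, "\\3", h))
    nsites <- as.integer(sub(rx, "\\4", h))
    evalue <- .parseNum(sub(rx, "\\5", h))
    mid <- sprintf("motif_%d", k)
    alt <- sprintf("MEME-%d", k)

    ## block boundaries: this motif's lines run to the next MOTIF header
    blockEnd <- min(c(motifAt[motifAt > at] - 1L, length(lines)))
    block <- lines[at:blockEnd]

    bayes <- NA_real_
    loLine <- grep("^log-odds matrix:", block, value = TRUE)
    if (length(loLine) && grepl("bayes=\\s*\\S+", loLine[1]))
      bayes <- .parseNum(sub(".*bayes=\\s*(\\S+).*", "\\1", loLine[1]))

    ## sites table
    sAt <- grep("sites sorted by position p-value", block)
    if (length(sAt)) {
      j <- sAt[1] + 1L                       # dashed line
      header <- block[j + 1L]
      hasStrand <- grepl("\\bStrand\\b", header)
      j <- j + 3L                            # first data row
      while (j <= length(block) && !grepl("^-{10,}", block[j]) &&
             nzchar(trimws(block[j]))) {
        tok <- strsplit(trimws(block[j]), "\\s+")[[1]]
        need <- 3L + as.integer(hasStrand)
        if (length(tok) < need)
          .formatError("malformed site row for motif ", name, ": ", block[j])
        sname <- tok[1]
        strand <- if (hasStrand) tok[2] else "none"
        start <- as.integer(tok[2L + as.integer(hasStrand)])
        pval <- .parseNum(tok[3L + as.integer(hasStrand)])
        rest <- tok[-seq_len(need)]
        L <- unname(lenByName[sname])
        if (is.na(L))
          .formatError("site row names unknown sequence '", sname,
                       "' for motif ", name)
        end <- start + width - 1L
        if (length(rest) == 3L) {
          lf <- rest[1]; site <- rest[2]; rf <- rest[3]
        } else if (length(rest) == 2L) {
          if (start == 1L) { lf <- ""; site <- rest[1]; rf <- rest[2] }
          else { lf <- rest[1]; site <- rest[2]; rf <- "" }
        } else if (length(rest) == 1L) {
          lf <- ""; site <- rest[1]; rf <- ""
        } else {
          .formatError("malformed site row for motif ", name, ": ", block[j])
        }
        if (nchar(site) != width)
          .formatError("motif ", name, " declares width ", width,
                       " but a site string has ", nchar(site), " letters")
        occ <- rbind(occ, data.frame(
          sequence_name = sname, sequence_length = L, motif_id = mid,
          start = start, end = end, strand = strand, p_value = pval,
          site_sequence = site, left_flank = lf, right_flank = rf,
          stringsAsFactors = FALSE))
        j <- j + 1L
      }
    }

    ## letter-probability matrix
    pAt <- grep("^letter-probability matrix:", block)
    if (length(pAt)) {
      meta <- block[pAt[1]]
      aw <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", meta))
      rows <- block[(pAt[1] + 1L):(pAt[1] + aw)]
      probs <- t(vapply(rows, function(r)
        .parseNum(strsplit(trimws(r), "\\s+")[[1]]), numeric(K)))
      probs <- t(probs)            # K x width
      dimnames(probs) <- list(letters, NULL)
      probs <- sweep(probs, 2, colSums(probs), "/")  # undo print rounding
      if (ncol(probs) != width)
        .formatError("probability matrix width disagrees with motif ", name)
      ppms[[mid]] <- new("PositionProbabilityMatrix", alphabet = letters,
                         probs = probs, nSites = max(1L, nsites))
    }

    motifs <- rbind(motifs, data.frame(
      motif_id = mid, name = name, alt = alt, width = width,
      nsites = nsites, e_value = evalue, bayes_threshold = bayes,
      stringsAsFactors = FALSE))
  }

  res <- new("MemeResult", version = version, alphabet = alphabet,
             letters = letters, background = background, commandLine = cmd,
             sequences = sequences, motifs = motifs, ppms = ppms,
             occurrences = .orderOccurrences(occ),
             scannedSites = .emptyScannedSites())
  validObject(res)
  res
}

#' Read a MEME results file, sniffing the dialect
#'
#' Dispatches to [parseMemeXML()] or [parseMemeText()]. With
#' `format = "auto"` the first bytes decide: a leading `<` means XML, a
#' `MEME version` header means text.
#'
#' @param path Path to a MEME results file.
#' @param format `"auto"`, `"xml"` or `"txt"`.
#' @return A [MemeResult-class].
#' @export
readMeme <- function(path, format = c("auto", "xml", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) .ioError("file not found: ", path)
  if (format == "auto") {
    head <- readLines(path, n = 20L, warn = FALSE)
    first <- trimws(head[nzchar(trimws(head))][1])
    format <- if (startsWith(first, "<")) "xml"
              else if (any(grepl("^MEME version ", head))) "txt"
              else .formatError("cannot sniff MEME dialect of ", path,
                                ": neither XML nor a 'MEME version' header")
  }
  switch(format, xml = parseMemeXML(path), txt = parseMemeText(path))
}
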