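# Hand-written minimal XML fixture: one width-7 motif planted at 0-based
# offset 9 on a length-100 protein sequence.
miniXML <- function(version = "5.4.1", offset = 9L, width = 7L,
                    seqName = "AT4G36920.2", motifs = TRUE) {
  letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y")
  site <- rep("A", width)
  ppmCols <- paste(vapply(seq_len(width), function(j) paste0(
    "<alphabet_array>",
    paste(sprintf('<value letter_id="%s">%.6f</value>', letters,
                  c(1, rep(0, 19))), collapse = ""),
    "</alphabet_array>"), character(1)), collapse = "")
  motifBlock <- if (motifs) paste0(
    '<motif id="motif_1" name="AAAAAAA" alt="MEME-1" width="', width,
    '" sites="1" ic="10" re="10" llr="10" p_value="1e-10" e_value="2.5e-05" bayes_threshold="8.5" elapsed_time="1">',
    "<probabilities><alphabet_matrix>", ppmCols,
    "</alphabet_matrix></probabilities>",
    "<contributing_sites>",
    '<contributing_site sequence_id="sequence_0" position="', offset,
    '" strand="none" pvalue="1.20e-09">',
    "<left_flank>MK</left_flank><site>",
    paste(sprintf('<letter_ref letter_id="%s"/>', site), collapse = ""),
    "</site><right_flank>LL</right_flank></contributing_site>",
    "</contributing_sites></motif>") else ""
  paste0(
    '<?xml version="1.0"?><MEME version="', version, '">',
    '<training_set primary_sequences="x.fa" primary_count="1" primary_positions="100">',
    '<alphabet name="Protein" like="protein">',
    paste(sprintf('<letter id="%s" symbol="%s"/>', letters, letters),
          collapse = ""),
    "</alphabet>",
    '<sequence id="sequence_0" name="', seqName,
    '" length="100" weight="1.000000"/>',
    "<letter_frequencies><alphabet_array>",
    paste(sprintf('<value letter_id="%s">%.6f</value>', letters,
                  rep(0.05, 20)), collapse = ""),
    "</alphabet_array></letter_frequencies></training_set>",
    "<model><command_line>meme x.fa -protein</command_line></model>",
    "<motifs>", motifBlock, "</motifs></MEME>")
}

writeTemp <- function(text, ext = ".xml") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("XML 0-based offsets become 1-based inclusive coordinates", {
  res <- parseMemeXML(writeTemp(miniXML(offset = 9L, width = 7L)))
  occ <- occurrenceTable(res)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$start, 10L)
  expect_identical(occ$end, 16L)
  expect_identical(occ$strand, "none")
  expect_identical(occ$left_flank, "MK")
  expect_identical(occ$p_value, 1.2e-09)
})

test_that("sequence names round-trip verbatim, dot included", {
  res <- parseMemeXML(writeTemp(miniXML(seqName = "AT4G36920.2")))
  expect_identical(trainingSequences(res)$name, "AT4G36920.2")
  expect_identical(occurrenceTable(res)$sequence_name, "AT4G36920.2")
})

test_that("zero-motif XML still populates sequences", {
  res <- parseMemeXML(writeTemp(miniXML(motifs = FALSE)))
  expect_identical(nrow(motifModels(res)), 0L)
  expect_identical(nrow(occurrenceTable(res)), 0L)
  expect_identical(nrow(trainingSequences(res)), 1L)
  expect_named(occurrenceTable(res),
               c("sequence_name", "sequence_length", "motif_id", "start",
                 "end", "strand", "p_value", "site_sequence",
                 "left_flank", "right_flank"))
})

test_that("non-5.x versions and malformed documents are rejected clearly", {
  expect_error(parseMemeXML(writeTemp(miniXML(version = "4.11.2"))),
               "4\\.11\\.2", class = "motifscapeFormatError")
  expect_error(parseMemeXML(writeTemp("<notmeme/>")),
               "MEME", class = "motifscapeFormatError")
  expect_error(parseMemeXML(writeTemp(
    '<MEME version="5.4.1"><motifs/></MEME>')),
    "training_set", class = "motifscapeFormatError")
  noMotifs <- sub("<motifs></motifs>", "",
                  miniXML(motifs = FALSE), fixed = TRUE)
  expect_error(parseMemeXML(writeTemp(noMotifs)),
               "motifs", class = "motifscapeFormatError")
  expect_error(parseMemeXML("no/such/file.xml"),
               "no/such/file.xml", class = "motifscapeIOError")
})

test_that("both dialects reproduce the planted truth exactly", {
  for (seed in c(2, 31)) {
    ds <- makeDataset(motifSimSpec(seed = seed, nSequences = 12L,
                                   nMotifs = 4L))
    want <- occurrenceTable(ds$truth)
    expect_identical(occurrenceTable(parseMemeXML(ds$files[["xml"]])), want)
    expect_identical(occurrenceTable(parseMemeText(ds$files[["txt"]])), want)
  }
})

test_that("XML and text parsers agree on all shared fields", {
  ds <- makeDataset(motifSimSpec(seed = 77, alphabet = "DNA",
                                 nSequences = 10L, nMotifs = 3L))
  rx <- parseMemeXML(ds$files[["xml"]])
  rt <- parseMemeText(ds$files[["txt"]])
  expect_identical(occurrenceTable(rx), occurrenceTable(rt))
  expect_identical(trainingSequences(rx), trainingSequences(rt))
  expect_identical(motifModels(rx), motifModels(rt))
  expect_identical(memeAlphabet(rx), memeAlphabet(rt))
  expect_equal(backgroundFrequencies(rx), backgroundFrequencies(rt),
               tolerance = 1e-4)
  for (id in motifModels(rx)$motif_id)
    expect_equal(ppmMatrix(motifPPM(rx, id)), ppmMatrix(motifPPM(rt, id)),
                 tolerance = 1e-4)
})

test_that("coordinate invariant: span equals motif width in both dialects", {
  ds <- makeDataset(motifSimSpec(seed = 4, alphabet = "RNA",
                                 nSequences = 8L, nMotifs = 5L))
  for (f in c("xml", "txt")) {
    res <- readMeme(ds$files[[f]])
    occ <- occurrenceTable(res)
    w <- motifModels(res)$width[match(occ$motif_id,
                                      motifModels(res)$motif_id)]
    expect_identical(occ$end - occ$start + 1L, w)
    expect_identical(nchar(occ$site_sequence), as.integer(w))
  }
})

test_that("text parser reads counts, strands and Bayes thresholds", {
  spec <- motifSimSpec(seed = 21, nSequences = 6L, nMotifs = 3L,
                       siteProb = 1)
  ds <- makeDataset(spec)
  res <- parseMemeText(ds$files[["txt"]])
  expect_identical(nrow(motifModels(res)), 3L)
  expect_identical(nrow(occurrenceTable(res)), 18L)  # ZOOPS, prob 1
  expect_true(all(occurrenceTable(res)$strand == "none"))  # protein
  expect_identical(motifModels(res)$bayes_threshold,
                   motifModels(ds$truth)$bayes_threshold)
  for (id in motifModels(res)$motif_id)
    expect_identical(ncol(ppmMatrix(motifPPM(res, id))),
                     motifModels(res)$width[match(id, motifModels(res)$motif_id)])
})

test_that("text dialect errors: missing header, width mismatch", {
  expect_error(parseMemeText(writeTemp("not a meme file\n", ".txt")),
               "MEME version", class = "motifscapeFormatError")
  ds <- makeDataset(motifSimSpec(seed = 3, nSequences = 4L, nMotifs = 1L,
                                 siteProb = 1, widthRange = c(5L, 5L)))
  lines <- readLines(ds$files[["txt"]])
  # corrupt the declared width, leaving the site strings at 5 letters
  lines <- sub("width =   5", "width =   6", lines, fixed = TRUE)
  expect_error(parseMemeText(writeTemp(paste(lines, collapse = "\n"), ".txt")),
               "width", class = "motifscapeFormatError")
})

test_that("the scanned-sites summary is parsed but kept separate", {
  ds <- makeDataset(motifSimSpec(seed = 6, nSequences = 7L, nMotifs = 2L))
  res <- parseMemeXML(ds$files[["xml"]])
  ss <- scannedSites(res)
  expect_identical(nrow(ss), nrow(occurrenceTable(res)))
  expect_named(ss, c("sequence_name", "motif_id", "start", "strand",
                     "p_value"))
  # text dialect has no summary
  expect_identical(nrow(scannedSites(parseMemeText(ds$files[["txt"]]))), 0L)
})

test_that("readMeme sniffs the dialect from the first bytes", {
  ds <- makeDataset(motifSimSpec(seed = 9, nSequences = 5L, nMotifs = 2L))
  expect_identical(occurrenceTable(readMeme(ds$files[["xml"]])),
                   occurrenceTable(readMeme(ds$files[["txt"]])))
  expect_error(readMeme(writeTemp("garbage", ".bin")),
               "sniff", class = "motifscapeFormatError")
})
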