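test_that("ppm estimation matches a hand tally", {
  ppm <- sitesToPPM(c("AC", "AC", "AT", "GC"), "DNA")
  m <- ppmMatrix(ppm)
  expect_equal(unname(m["A", 1]), 0.75)
  expect_equal(unname(m["G", 1]), 0.25)
  expect_equal(unname(m["C", 2]), 0.75)
  expect_equal(unname(m["T", 2]), 0.25)
  expect_identical(nSites(ppm), 4L)
  expect_equal(colSums(m), c(1, 1))
})

test_that("a single site gives degenerate columns; pseudocount smooths", {
  m <- ppmMatrix(sitesToPPM("ACGT", "DNA"))
  expect_equal(diag(m[c("A", "C", "G", "T"), ]), c(1, 1, 1, 1),
               ignore_attr = TRUE)
  ms <- ppmMatrix(sitesToPPM("ACGT", "DNA", pseudocount = 1))
  expect_equal(unname(ms["A", 1]), 2 / 5)
  expect_equal(unname(ms["C", 1]), 1 / 5)
  expect_equal(colSums(ms), rep(1, 4), ignore_attr = TRUE)
})

test_that("ragged or alien inputs are rejected with a pointer", {
  expect_error(sitesToPPM(c("ACG", "AC"), "DNA"), "site 2")
  expect_error(sitesToPPM(c("ACG", "AXG"), "DNA"), "X")
  expect_error(sitesToPPM(character(0), "DNA"), "at least one")
})

test_that("information content matches closed forms", {
  uniform <- sitesToPPM(c("A", "C", "G", "T"), "DNA")
  expect_equal(logoIC(informationContent(uniform)), 0)
  degenerate <- sitesToPPM(c("A", "A"), "DNA")
  expect_equal(logoIC(informationContent(degenerate)), 2)
  half <- sitesToPPM(c("A", "C"), "DNA")
  lg <- informationContent(half)
  expect_equal(logoIC(lg), 1)
  expect_equal(unname(logoHeights(lg)["A", 1]), 0.5)
  expect_equal(unname(logoHeights(lg)["C", 1]), 0.5)
})

test_that("small-sample correction equals (K-1)/(2 ln2 n) and vanishes", {
  expect_equal(smallSampleCorrection(4, 20), 3 / (2 * log(2) * 20),
               tolerance = 1e-12)
  sites20 <- rep(c("A", "C", "G", "T"), 5)
  ppm <- sitesToPPM(sites20, "DNA")
  expect_identical(nSites(ppm), 20L)
  # uniform column: uncorrected IC is 0; the corrected one is clipped at 0
  expect_equal(logoIC(informationContent(ppm, TRUE)), 0)
  deg <- sitesToPPM(rep("A", 20), "DNA")
  expect_equal(logoIC(informationContent(deg, TRUE)),
               2 - 3 / (2 * log(2) * 20), tolerance = 1e-9)
  # n -> infinity: correction -> 0
  big <- new("PositionProbabilityMatrix", alphabet = c("A", "C", "G", "T"),
             probs = matrix(c(1, 0, 0, 0)), nSites = 1000000L)
  expect_equal(logoIC(informationContent(big, TRUE)),
               logoIC(informationContent(big, FALSE)), tolerance = 1e-5)
})

test_that("stack heights always sum to the column IC and stay in bounds", {
  set.seed(7)
  for (i in 1:200) {
    K <- sample(c(4L, 20L), 1)
    letters <- if (K == 4L) c("A", "C", "G", "T") else
      motifscape:::.ALPHABETS$PROTEIN
    p <- matrix(stats::rgamma(K * 3, 0.4), nrow = K)
    p <- sweep(p, 2, colSums(p), "/")
    ppm <- new("PositionProbabilityMatrix", alphabet = letters, probs = p,
               nSites = sample(2:100, 1))
    for (corr in c(FALSE, TRUE)) {
      lg <- informationContent(ppm, corr)
      expect_lt(max(abs(colSums(logoHeights(lg)) - logoIC(lg))), 1e-9)
      expect_true(all(logoIC(lg) >= 0 & logoIC(lg) <= log2(K) + 1e-12))
    }
  }
})

test_that("permuting site order changes neither ppm nor logo", {
  truth <- simulateMotifData(motifSimSpec(seed = 30, nSequences = 15L))
  sites <- occurrenceTable(truth)$site_sequence[
    occurrenceTable(truth)$motif_id == "motif_1"]
  set.seed(1)
  shuffled <- sample(sites)
  a <- sitesToPPM(sites, "PROTEIN")
  b <- sitesToPPM(shuffled, "PROTEIN")
  expect_identical(ppmMatrix(a), ppmMatrix(b))
  expect_identical(logoHeights(informationContent(a)),
                   logoHeights(informationContent(b)))
})

test_that("motifLogo uses parsed sites and warns on a disagreeing ppm", {
  ds <- makeDataset(motifSimSpec(seed = 18, nSequences = 10L, nMotifs = 2L))
  res <- parseMemeXML(ds$files[["xml"]])
  expect_no_warning(lg <- motifLogo(res, "motif_1"))
  want <- sitesToPPM(
    occurrenceTable(res)$site_sequence[
      occurrenceTable(res)$motif_id == "motif_1"], "PROTEIN")
  expect_equal(ppmMatrix(lg@ppm), ppmMatrix(want))
  # corrupt the stored matrix beyond the 0.01 tolerance
  tweaked <- res
  m <- ppmMatrix(tweaked@ppms[["motif_1"]])
  m[, 1] <- rev(m[, 1])
  if (max(abs(m - ppmMatrix(tweaked@ppms[["motif_1"]]))) > 0.01) {
    tweaked@ppms[["motif_1"]]@probs <- m
    expect_warning(motifLogo(tweaked, "motif_1"), "disagrees")
  }
  expect_error(motifLogo(res, "motif_99"), "unknown motif")
})

test_that("the rendered logo carries one glyph per nonzero-height letter", {
  ppm <- sitesToPPM(c("AC", "AC", "AT", "GC"), "DNA")
  fig <- renderLogo(informationContent(ppm))
  # column 1: A and G; column 2: C and T -> 4 letters drawn
  expect_identical(attr(fig, "logoLetterCount"), 4L)
  f <- withr::local_tempfile(fileext = ".svg")
  saveFigure(fig, f, width = 4, height = 3)
  svg <- xml2::read_xml(f)
  expect_identical(xml2::xml_name(svg), "svg")
})

test_that("an all-uniform (zero IC) logo renders empty stacks, not an error", {
  uniform <- sitesToPPM(c("AAA", "CCC", "GGG", "TTT"), "DNA")
  fig <- renderLogo(informationContent(uniform))
  expect_identical(attr(fig, "logoLetterCount"), 0L)
  expect_s3_class(fig, "ggplot")
})

test_that("the y-axis tops out at log2(K)", {
  prot <- sitesToPPM(strrep("A", 7), "PROTEIN")
  fig <- renderLogo(informationContent(prot))
  ylim <- ggplot2::ggplot_build(fig)$layout$panel_params[[1]]$y.range
  expect_equal(max(ylim), log2(20))
})
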