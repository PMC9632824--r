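test_that("a 20-sequence / 37-occurrence table yields 20 rows and 37 boxes", {
  tab <- makeOccurrenceTable(nSeq = 20L, nOcc = 37L)
  layout <- buildTracks(tab)
  expect_identical(nrow(trackRows(layout)), 20L)
  expect_identical(nrow(trackBoxes(layout)), 37L)

  f <- withr::local_tempfile(fileext = ".json")
  writeTrackLayoutJSON(layout, f)
  dump <- jsonlite::read_json(f)
  expect_length(dump$rows, 20L)
  expect_length(dump$boxes, 37L)
  expect_identical(dump$x_max, max(tab$sequence_length))
})

test_that("box count always equals table row count", {
  for (seed in c(1, 22)) {
    truth <- simulateMotifData(motifSimSpec(seed = seed, nSequences = 9L))
    tab <- occurrenceTable(truth)
    expect_identical(nrow(trackBoxes(buildTracks(tab))), nrow(tab))
  }
})

test_that("default row order is first appearance; explicit order permutes boxes", {
  tab <- makeOccurrenceTable(nSeq = 6L, nOcc = 12L)
  layout <- buildTracks(tab)
  expect_identical(trackRows(layout)$sequence_name,
                   unique(tab$sequence_name))
  rev_ <- rev(trackRows(layout)$sequence_name)
  layoutR <- buildTracks(tab, rowOrder = rev_)
  expect_identical(trackRows(layoutR)$sequence_name, rev_)
  a <- trackBoxes(layout); b <- trackBoxes(layoutR)
  a$name <- trackRows(layout)$sequence_name[a$row]
  b$name <- trackRows(layoutR)$sequence_name[b$row]
  key <- function(d) d[order(d$name, d$start, d$motif_id),
                       c("name", "motif_id", "start", "end", "strand")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("row-order intersection warns per missing name and errors when empty", {
  tab <- makeOccurrenceTable(nSeq = 4L, nOcc = 8L)
  names_ <- unique(tab$sequence_name)
  ws <- capture_warnings(
    layout <- buildTracks(tab, rowOrder = c(names_[2:4], "ghost")))
  expect_length(ws, 2L)  # "ghost" unknown + names_[1] dropped
  expect_true(any(grepl("ghost", ws)))
  expect_true(any(grepl(names_[1], ws, fixed = TRUE)))
  expect_identical(trackRows(layout)$sequence_name, names_[2:4])

  expect_error(buildTracks(tab, rowOrder = c("u", "v")), "share no",
               class = "motifscapeUsageError")
  expect_error(buildTracks(tab[0, ]), "empty",
               class = "motifscapeUsageError")
})

test_that("the color map is a pure function of the sorted motif set", {
  ids <- c("motif_2", "motif_1", "motif_3")
  expect_identical(motifColorMap(ids), motifColorMap(rev(ids)))
  expect_identical(motifColorMap(c(ids, ids)), motifColorMap(ids))
  expect_identical(length(unique(motifColorMap(sprintf("m%d", 1:12)))), 12L)
  expect_warning(big <- motifColorMap(sprintf("m%02d", 1:15)), "cycle")
  expect_length(big, 15L)
})

test_that("rendering without a tree returns a plain track panel", {
  tab <- makeOccurrenceTable(nSeq = 5L, nOcc = 9L)
  fig <- renderLocations(buildTracks(tab))
  expect_s3_class(fig, "ggplot")
  f <- withr::local_tempfile(fileext = ".svg")
  saveFigure(fig, f)
  expect_identical(xml2::xml_name(xml2::read_xml(f)), "svg")
})

test_that("tree-ordered figures share row order with the tree", {
  ds <- makeDataset(motifSimSpec(seed = 14, nSequences = 10L, nMotifs = 3L,
                                 siteProb = 1))
  tab <- occurrenceTable(parseMemeXML(ds$files[["xml"]]))
  tr <- readNewickTree(ds$files[["tree"]])
  fig <- plotMotifLocations(tab, tree = tr)
  layout <- attr(fig, "trackLayout")
  expect_identical(trackRows(layout)$sequence_name, leafOrder(tr))
  # same multiset of boxes as the unordered figure
  plain <- buildTracks(tab)
  nm <- function(l) {
    b <- trackBoxes(l)
    b$name <- trackRows(l)$sequence_name[b$row]
    b <- b[order(b$name, b$start, b$motif_id), ]
    rownames(b) <- NULL
    b[, c("name", "motif_id", "start", "end")]
  }
  expect_identical(nm(layout), nm(plain))
})

test_that("convenience call equals the manual composition", {
  ds <- makeDataset(motifSimSpec(seed = 25, nSequences = 8L, nMotifs = 2L))
  tab <- occurrenceTable(parseMemeXML(ds$files[["xml"]]))
  manualLayout <- buildTracks(tab)
  auto <- plotMotifLocations(tab)
  expect_identical(trackRows(attr(auto, "trackLayout")),
                   trackRows(manualLayout))
  expect_identical(trackBoxes(attr(auto, "trackLayout")),
                   trackBoxes(manualLayout))
})

test_that("a tree missing 2 tips and adding 2 builds on the intersection with 4 warnings", {
  ds <- makeDataset(motifSimSpec(seed = 16, nSequences = 20L, nMotifs = 5L,
                                 siteProb = 0.9),
                    treeDrop = 2L, treeAdd = 2L)
  tab <- occurrenceTable(parseMemeXML(ds$files[["xml"]]))
  # with siteProb 0.9 over 5 motifs every sequence gets >=1 site here
  expect_identical(length(unique(tab$sequence_name)), 20L)
  ws <- capture_warnings(
    fig <- plotMotifLocations(tab, tree = ds$files[["tree"]]))
  expect_length(ws, 4L)
  expect_identical(sum(grepl("alien", ws)), 2L)       # tree-only names
  expect_identical(sum(grepl("dropped", ws)), 2L)     # table-only names
  layout <- attr(fig, "trackLayout")
  expect_identical(nrow(trackRows(layout)), 18L)
  tr <- readNewickTree(ds$files[["tree"]])
  keep <- intersect(leafOrder(tr), unique(tab$sequence_name))
  expect_identical(trackRows(layout)$sequence_name, keep)
})

test_that("tip annotations add a keyed point layer with one color per level", {
  ds <- makeDataset(motifSimSpec(seed = 19, nSequences = 8L, nMotifs = 3L,
                                 siteProb = 1))
  tab <- occurrenceTable(parseMemeXML(ds$files[["xml"]]))
  fig <- plotMotifLocations(tab, tree = ds$files[["tree"]],
                            annotations = ds$files[["anno"]])
  expect_s3_class(fig, "patchwork")
  anno <- read.delim(ds$files[["anno"]])
  treePanel <- fig[[1]]
  built <- ggplot2::ggplot_build(treePanel)
  pts <- built$data[[length(built$data)]]
  expect_identical(nrow(pts), 8L)  # one point per tip
  expect_identical(length(unique(pts$colour)),
                   length(unique(anno$Group)))
})

test_that("renderLocations refuses a tree that disagrees with the layout", {
  tab <- makeOccurrenceTable(nSeq = 4L, nOcc = 6L)
  layout <- buildTracks(tab)
  tr <- readNewickTree("((p,q),(r,s));")
  expect_error(renderLocations(layout, tree = tr), "does not match",
               class = "motifscapeUsageError")
})
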