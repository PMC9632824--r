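## Motif-location maps: one horizontal track per sequence, one colored box
## per occurrence, optionally row-ordered by and drawn beside a tree.

.TRACK_PALETTE <- c("#4E79A7", "#F28E2B", "#E15759", "#76B7B2", "#59A14F",
                    "#EDC948", "#B07AA1", "#FF9DA7", "#9C755F", "#BAB0AC",
                    "#1B9E77", "#7570B3")

#' Stable motif-id color map
#'
#' A pure function of the sorted motif-id set: the same motifs always get
#' the same colors, whatever order they arrive in. The 12-color categorical
#' palette cycles (with a warning) beyond 12 motifs.
#'
#' @param motifIds Character vector of motif ids.
#' @return Named character vector motif_id -> color.
#' @export
motifColorMap <- function(motifIds) {
  ids <- sort(unique(motifIds))
  if (length(ids) > length(.TRACK_PALETTE))
    warning("more than ", length(.TRACK_PALETTE),
            " motifs; the categorical palette cycles and colors repeat",
            call. = FALSE)
  cols <- rep_len(.TRACK_PALETTE, length(ids))
  stats::setNames(cols, ids)
}

#' Resolve the geometry of a motif-location figure
#'
#' Turns an occurrence table into a [TrackLayout-class]: one row per
#' sequence (default order: first appearance in the table), one box per
#' occurrence. When `rowOrder` is supplied, rows are reordered to match it
#' and restricted to the intersection of the two name sets; every name
#' present on only one side is reported in its own warning, and an empty
#' intersection is an error listing both sets.
#'
#' @param table Occurrence table (see [occurrenceTable()]).
#' @param rowOrder Optional character vector of sequence names, e.g. a
#'   tree's [leafOrder()].
#' @return A [TrackLayout-class].
#' @examples
#' truth <- simulateMotifData(motifSimSpec(seed = 1, nSequences = 6))
#' buildTracks(occurrenceTable(truth))
#' @export
buildTracks <- function(table, rowOrder = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    .usageError("nothing to plot: the occurrence table is empty")
  need <- c("sequence_name", "sequence_length", "motif_id", "start", "end")
  missing <- setdiff(need, names(table))
  if (length(missing))
    .usageError("occurrence table lacks column(s): ",
                paste(missing, collapse = ", "))
  if (!"strand" %in% names(table)) table$strand <- "none"

  firstSeen <- !duplicated(table$sequence_name)
  rows <- data.frame(sequence_name = table$sequence_name[firstSeen],
                     sequence_length = as.integer(table$sequence_length[firstSeen]),
                     stringsAsFactors = FALSE)
  if (!is.null(rowOrder)) {
    rowOrder <- as.character(rowOrder)
    common <- intersect(rowOrder, rows$sequence_name)
    if (length(common) == 0L)
      .usageError("row order and occurrence table share no sequence names; ",
                  "row order has {", paste(rowOrder, collapse = ", "),
                  "}, table has {",
                  paste(rows$sequence_name, collapse = ", "), "}")
    for (nm in setdiff(rowOrder, rows$sequence_name))
      warning("row-order name not in the occurrence table: ", nm,
              call. = FALSE)
    for (nm in setdiff(rows$sequence_name, rowOrder))
      warning("sequence not in the row order, dropped: ", nm, call. = FALSE)
    rows <- rows[match(common, rows$sequence_name), , drop = FALSE]
  }
  rows$y <- seq_len(nrow(rows))
  rownames(rows) <- NULL

  kept <- table[table$sequence_name %in% rows$sequence_name, , drop = FALSE]
  boxes <- data.frame(row = match(kept$sequence_name, rows$sequence_name),
                      motif_id = kept$motif_id,
                      start = as.integer(kept$start),
                      end = as.integer(kept$end),
                      strand = kept$strand, stringsAsFactors = FALSE)
  boxes <- boxes[order(boxes$row, boxes$start), , drop = FALSE]
  rownames(boxes) <- NULL

  layout <- new("TrackLayout", rows = rows, boxes = boxes,
                xMax = max(rows$sequence_length),
                colorMap = motifColorMap(boxes$motif_id))
  validObject(layout)
  layout
}

#' Render a motif-location map
#'
#' Each sequence is a thin backbone line spanning positions 1 to its length
#' on a shared axis (shorter sequences end earlier); each occurrence is a
#' translucent filled box colored by motif id, later-starting boxes drawn
#' on top; minus-strand occurrences carry a `<` glyph. With a tree, a left
#' panel shows the rectangular tree sharing row y-coordinates with the
#' tracks, sequence names sitting between the panels; tip-annotation points
#' (colored by `annoColumn`) are drawn at the tips.
#'
#' @param layout A [TrackLayout-class].
#' @param tree Optional [ape::phylo]; its tips must equal the layout's
#'   rows, in [leafOrder()] order (use [plotMotifLocations()] to have the
#'   intersection wired automatically).
#' @param annotations Optional tip-annotation data.frame (first column =
#'   tip label), drawn as tip points.
#' @param annoColumn Annotation column to color tip points by; default the
#'   first non-label column.
#' @return A `ggplot`/`patchwork` object; write it with [saveFigure()].
#' @export
renderLocations <- function(layout, tree = NULL, annotations = NULL,
                            annoColumn = NULL) {
  stopifnot(is(layout, "TrackLayout"))
  rows <- layout@rows
  boxes <- layout@boxes
  boxes$y <- rows$y[boxes$row]

  tracks <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = data.frame(x = 1, xend = rows$sequence_length, y = rows$y),
      ggplot2::aes(x = x, xend = xend, y = y, yend = y),
      linewidth = 0.4, color = "grey55") +
    ggplot2::geom_rect(
      data = cbind(boxes,
                   xmin = boxes$start - 0.5, xmax = boxes$end + 0.5,
                   ymin = boxes$y - 0.32, ymax = boxes$y + 0.32),
      ggplot2::aes(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                   fill = motif_id),
      alpha = 0.85, color = NA) +
    ggplot2::scale_fill_manual(values = layout@colorMap, name = "motif") +
    ggplot2::scale_y_reverse(breaks = rows$y, labels = rows$sequence_name,
                             limits = c(nrow(rows) + 0.6, 0.4),
                             expand = c(0, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, layout@xMax * 1.02),
                                expand = c(0.01, 0)) +
    ggplot2::labs(x = "position", y = NULL) +
    ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(axis.line.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
  minus <- boxes[boxes$strand == "-", , drop = FALSE]
  if (nrow(minus)) {
    tracks <- tracks + ggplot2::geom_text(
      data = minus, ggplot2::aes(x = start, y = y), label = "<",
      size = 2.4, vjust = 0.5)
  }
  if (is.null(tree)) return(tracks)

  ord <- leafOrder(tree)
  if (!identical(ord, rows$sequence_name))
    .usageError("tree tip order does not match the layout rows; ",
                "tips: {", paste(ord, collapse = ", "), "}, rows: {",
                paste(rows$sequence_name, collapse = ", "), "}")
  tl <- treeLayout(tree)
  nodes <- tl$nodes
  seg <- nodes[!is.na(nodes$parent), , drop = FALSE]
  seg$px <- nodes$x[seg$parent]
  seg$py <- nodes$y[seg$parent]
  panel <- ggplot2::ggplot() +
    ## horizontal branch into each node, vertical connector at the parent
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = px, xend = x, y = y, yend = y),
      linewidth = 0.4, color = "grey20") +
    ggplot2::geom_segment(data = seg,
      ggplot2::aes(x = px, xend = px, y = py, yend = y),
      linewidth = 0.4, color = "grey20") +
    ggplot2::scale_y_reverse(limits = c(nrow(rows) + 0.6, 0.4),
                             expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0.02, 0)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void(base_size = 11)
  if (!is.null(annotations)) {
    joined <- joinTipAnnotations(tree, annotations)
    anno <- joined$matched
    if (nrow(anno)) {
      if (is.null(annoColumn))
        annoColumn <- setdiff(names(anno), "label")[1]
      if (is.null(annoColumn) || !annoColumn %in% names(anno))
        .usageError("annotation column not found: ",
                    if (is.null(annoColumn)) "<none>" else annoColumn)
      tipNodes <- nodes[nodes$isTip, , drop = FALSE]
      anno$x <- tipNodes$x[match(anno$label, tipNodes$label)]
      anno$y <- tipNodes$y[match(anno$label, tipNodes$label)]
      anno$.anno <- as.factor(anno[[annoColumn]])
      panel <- panel + ggplot2::geom_point(
        data = anno, ggplot2::aes(x = x, y = y, color = .anno), size = 2) +
        ggplot2::scale_color_manual(
          name = annoColumn,
          values = stats::setNames(
            rep_len(c("#7EC8E3", "#F28E2B", "#59A14F", "#B07AA1"),
                    nlevels(anno$.anno)),
            levels(anno$.anno)))
    }
  }
  patchwork::wrap_plots(panel, tracks, nrow = 1, widths = c(1, 2.6))
}

#' One-call motif-location figure
#'
#' Convenience composition of [readNewickTree()], [leafOrder()],
#' [buildTracks()] and [renderLocations()]: parses the tree and annotation
#' inputs when given, orders the tracks by the tree's leaf order (pruning
#' the tree and the table to their common names, with warnings), and
#' renders.
#'
#' @param table Occurrence table, or path to a TSV written by
#'   [writeOccurrenceTSV()].
#' @param tree Optional [ape::phylo], Newick string or `.nwk` path.
#' @param annotations Optional data.frame or TSV/CSV path (first column =
#'   tip label).
#' @param annoColumn,ladderize Passed through.
#' @return A `ggplot`/`patchwork` object with the [TrackLayout-class]
#'   attached as attribute `"trackLayout"`.
#' @examples
#' d <- file.path(tempdir(), "plotdemo")
#' files <- simulateMemeDataset(d, motifSimSpec(seed = 11, nSequences = 6))
#' tab <- occurrenceTable(parseMemeXML(files[["xml"]]))
#' fig <- plotMotifLocations(tab, tree = files[["tree"]])
#' @export
plotMotifLocations <- function(table, tree = NULL, annotations = NULL,
                               annoColumn = NULL, ladderize = "none") {
  if (is.character(table) && length(table) == 1L)
    table <- readOccurrenceTSV(table)
  phy <- NULL
  if (!is.null(tree))
    phy <- if (inherits(tree, "phylo")) tree else readNewickTree(tree)
  anno <- NULL
  if (!is.null(annotations)) {
    anno <- if (is.data.frame(annotations)) annotations
            else .readAnnotationTable(annotations)
  }
  if (is.null(phy)) {
    layout <- buildTracks(table)
    fig <- renderLocations(layout)
  } else {
    ord <- leafOrder(phy, ladderize = ladderize)
    layout <- buildTracks(table, rowOrder = ord)
    extra <- setdiff(phy$tip.label, layout@rows$sequence_name)
    if (length(extra))
      phy <- ape::drop.tip(phy, extra)  # names already reported above
    fig <- renderLocations(layout, tree = phy, annotations = anno,
                           annoColumn = annoColumn)
  }
  attr(fig, "trackLayout") <- layout
  fig
}

## TSV/CSV sniffing reader for tip-annotation tables.
.readAnnotationTable <- function(path) {
  if (!file.exists(path)) .ioError("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a TrackLayout as JSON
#'
#' Dumps rows, boxes, x_max and the color map — the figure geometry a test
#' or external tool can assert on without rendering.
#'
#' @param layout A [TrackLayout-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrackLayoutJSON <- function(layout, path) {
  stopifnot(is(layout, "TrackLayout"))
  obj <- list(rows = layout@rows, boxes = layout@boxes,
              x_max = layout@xMax, color_map = as.list(layout@colorMap))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a figure to SVG or PNG
#'
#' The format follows the file extension: `.svg` (cairo SVG device) or
#' `.png`.
#'
#' @param fig A `ggplot`/`patchwork` object.
#' @param path Output path ending in `.svg` or `.png`.
#' @param width,height Device size in inches.
#' @param dpi PNG resolution.
#' @return `path`, invisibly.
#' @export
saveFigure <- function(fig, path, width = 9, height = 6, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width, height = height,
                         units = "in", res = dpi),
    .usageError("unsupported figure format '.", ext, "'; use .svg or .png"))
  on.exit(grDevices::dev.off())
  print(fig)
  invisible(path)
}
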