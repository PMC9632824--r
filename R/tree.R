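## Newick handling: parsing (via ape behind this surface), leaf order,
## rectangular layout, and tip-annotation joining.

#' Read a Newick tree
#'
#' Accepts a file path or a Newick string. The input is pre-validated
#' (balanced parentheses, terminating `;`) so syntax errors carry a
#' character offset; duplicate tip labels are rejected by name. Trees are
#' treated as rooted as written; absent branch lengths are stored as 0;
#' bare numbers on internal nodes (support values) are kept as internal
#' labels; children keep their written order.
#'
#' Only Newick is supported — not Nexus or PhyloXML.
#'
#' @param x Path to a `.nwk` file, or a Newick string (recognized by the
#'   presence of `(` ... `;`).
#' @return An [ape::phylo] object.
#' @examples
#' tr <- readNewickTree("((A:1,B:1):1,C:2);")
#' leafOrder(tr)
#' @export
readNewickTree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (grepl("[(;]", x) && !file.exists(x)) {
    x
  } else {
    if (!file.exists(x)) .ioError("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        .formatError("unbalanced ')' at character ", i, " of the Newick input")
    }
  }
  if (depth != 0L)
    .formatError("unbalanced parentheses in the Newick input (", depth,
                 " '(' left open)")
  if (!grepl(";\\s*$", text))
    .formatError("Newick input does not end with ';' (last character at offset ",
                 nchar(text), ")")
  tree <- tryCatch(ape::read.tree(text = text), error = function(e)
    .formatError("Newick parse failed: ", conditionMessage(e)))
  if (is.null(tree)) .formatError("Newick parse failed on: ", text)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    .formatError("duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    .formatError("negative branch length in the Newick input")
  tree
}

#' Top-to-bottom tip order of a drawn tree
#'
#' Depth-first traversal with children in written file order (no
#' ladderization unless requested), i.e. the row order the motif-location
#' tracks adopt when drawn beside the tree.
#'
#' @param tree An [ape::phylo] object.
#' @param ladderize `"none"` (default: written order), `"ascending"` or
#'   `"descending"` (by clade size, via [ape::ladderize()]).
#' @return Character vector of tip labels.
#' @export
leafOrder <- function(tree, ladderize = c("none", "ascending", "descending")) {
  ladderize <- match.arg(ladderize)
  stopifnot(inherits(tree, "phylo"))
  if (ladderize != "none")
    tree <- ape::ladderize(tree, right = (ladderize == "descending"))
  tree <- stats::reorder(tree, "cladewise")
  tips <- tree$edge[, 2][tree$edge[, 2] <= ape::Ntip(tree)]
  if (ape::Ntip(tree) == 1L) tips <- 1L
  tree$tip.label[tips]
}

#' Rectangular (cladogram) layout of a tree
#'
#' x is the cumulative branch length from the root; tip y values are the
#' consecutive integers 1..T in [leafOrder()] order (1 = top row), and each
#' internal node sits midway between the extreme y of its children.
#'
#' @param tree An [ape::phylo] object.
#' @param ladderize Passed to [leafOrder()].
#' @return A list with `nodes` (data.frame: `node`, `label`, `isTip`, `x`,
#'   `y`, `parent`) and `tipOrder` (character vector).
#' @export
treeLayout <- function(tree, ladderize = "none") {
  stopifnot(inherits(tree, "phylo"))
  if (ladderize != "none")
    tree <- ape::ladderize(tree, right = (ladderize == "descending"))
  tree <- stats::reorder(tree, "cladewise")
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  root <- nTip + 1L
  parent <- rep(NA_integer_, nNode)
  x <- rep(0, nNode)
  ## cladewise order guarantees a parent is visited before its children
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    parent[b] <- a
    x[b] <- x[a] + tree$edge.length[i]
  }
  order <- leafOrder(tree)
  y <- rep(NA_real_, nNode)
  y[match(order, tree$tip.label)] <- seq_along(order)
  ## postorder: children resolved before parents
  po <- rev(seq_len(nrow(tree$edge)))
  for (rep_ in 1:2) {  # two passes are enough for any rooted tree
    for (i in po) {
      a <- tree$edge[i, 1]
      kids <- tree$edge[tree$edge[, 1] == a, 2]
      if (all(!is.na(y[kids]))) y[a] <- (min(y[kids]) + max(y[kids])) / 2
    }
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep("", tree$Nnode))
  nodes <- data.frame(node = seq_len(nNode), label = labels,
                      isTip = seq_len(nNode) <= nTip, x = x, y = y,
                      parent = parent, stringsAsFactors = FALSE)
  list(nodes = nodes, tipOrder = order)
}

#' Join a tip-annotation table onto a tree
#'
#' Inner join on exact tip-label equality. Annotation rows whose label
#' matches no tip, and tips with no annotation row, are both reported —
#' one warning per name — never silently dropped.
#'
#' @param tree An [ape::phylo] object.
#' @param annotations data.frame whose first column (or a column named
#'   `label`/`tip_label`) holds tip labels; remaining columns are the
#'   annotation attributes.
#' @return A list: `matched` (data.frame, one row per annotated tip, in
#'   [leafOrder()] order), `unmatchedAnnotations` (labels in the table but
#'   not the tree), `unannotatedTips` (tips with no row).
#' @export
joinTipAnnotations <- function(tree, annotations) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.data.frame(annotations) || ncol(annotations) < 1L)
    .usageError("annotations must be a data.frame with a tip-label column")
  labCol <- intersect(c("label", "tip_label"), names(annotations))
  labCol <- if (length(labCol)) labCol[1] else names(annotations)[1]
  labels <- as.character(annotations[[labCol]])
  tips <- tree$tip.label
  unmatched <- setdiff(labels, tips)
  unannotated <- setdiff(tips, labels)
  for (u in unmatched)
    warning("annotation label not in the tree: ", u, call. = FALSE)
  for (u in unannotated)
    warning("tree tip without annotation: ", u, call. = FALSE)
  keep <- labels %in% tips
  matched <- annotations[keep, , drop = FALSE]
  names(matched)[names(matched) == labCol] <- "label"
  ord <- leafOrder(tree)
  matched <- matched[order(match(matched$label, ord)), , drop = FALSE]
  rownames(matched) <- NULL
  list(matched = matched, unmatchedAnnotations = unmatched,
       unannotatedTips = unannotated)
}
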