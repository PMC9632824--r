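## Position probability matrices and information-content sequence logos,
## computed from extracted motif site sequences.

#' Estimate a position probability matrix from aligned site sequences
#'
#' Tallies letters per column and normalizes:
#' `p_ik = (count_ik + pseudocount) / (n + K * pseudocount)`.
#' The default pseudocount of 0 makes the logo reflect the sites verbatim;
#' `1/K` is a common regularized alternative.
#'
#' @param sites Character vector of equal-length site sequences (>= 1).
#' @param alphabet `"DNA"`, `"RNA"`, `"PROTEIN"`, or a letter vector.
#' @param pseudocount Nonnegative real added to every cell count.
#' @return A [PositionProbabilityMatrix-class].
#' @examples
#' ppm <- sitesToPPM(c("AC", "AC", "AT", "GC"), "DNA")
#' ppmMatrix(ppm)
#' @export
sitesToPPM <- function(sites, alphabet, pseudocount = 0) {
  if (length(sites) < 1L) .usageError("need at least one site sequence")
  if (pseudocount < 0) .usageError("pseudocount must be nonnegative")
  letters <- .alphabetLetters(alphabet)
  K <- length(letters)
  w <- nchar(sites[1])
  bad <- which(nchar(sites) != w)
  if (length(bad))
    .usageError("site sequences have unequal lengths; first offender is site ",
                bad[1], " ('", sites[bad[1]], "', length ",
                nchar(sites[bad[1]]), " vs ", w, ")")
  mat <- do.call(rbind, strsplit(sites, ""))
  alien <- setdiff(unique(as.vector(mat)), letters)
  if (length(alien))
    .usageError("letter(s) outside the alphabet: ",
                paste(alien, collapse = ", "))
  n <- length(sites)
  probs <- vapply(seq_len(w), function(j) {
    counts <- table(factor(mat[, j], levels = letters))
    (as.numeric(counts) + pseudocount) / (n + K * pseudocount)
  }, numeric(K))
  probs <- matrix(probs, nrow = K, dimnames = list(letters, NULL))
  new("PositionProbabilityMatrix", alphabet = letters, probs = probs,
      nSites = as.integer(n))
}

#' Information content and letter heights of a motif
#'
#' Per column i, the information content is
#' `R_i = log2(K) - H_i - e(n)` (clipped below at 0), where
#' `H_i = -sum_k p_ik log2(p_ik)` (with `0 * log2(0) := 0`) and the
#' small-sample correction is `e(n) = (K - 1) / (2 ln(2) n)` when enabled,
#' 0 otherwise. Letter heights are `p_ik * R_i`, so every stack sums to its
#' column's information content.
#'
#' The correction defaults off, matching common logo-drawing practice.
#'
#' @param ppm A [PositionProbabilityMatrix-class].
#' @param smallSampleCorrection Logical; apply `e(n)`.
#' @return A [SequenceLogo-class].
#' @examples
#' ppm <- sitesToPPM(c("AC", "AC", "AT", "GC"), "DNA")
#' logo <- informationContent(ppm)
#' logoIC(logo)
#' @export
informationContent <- function(ppm, smallSampleCorrection = FALSE) {
  stopifnot(is(ppm, "PositionProbabilityMatrix"))
  validObject(ppm)
  p <- ppm@probs
  K <- length(ppm@alphabet)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  H <- -colSums(plogp)
  e <- if (smallSampleCorrection) (K - 1) / (2 * log(2) * ppm@nSites) else 0
  ic <- pmax(0, log2(K) - H - e)
  heights <- sweep(p, 2, ic, "*")
  new("SequenceLogo", ppm = ppm, ic = ic, heights = heights,
      correction = isTRUE(smallSampleCorrection))
}

#' @rdname informationContent
#' @param logo A [SequenceLogo-class].
#' @export
logoIC <- function(logo) {
  stopifnot(is(logo, "SequenceLogo"))
  logo@ic
}

#' @rdname informationContent
#' @export
logoHeights <- function(logo) {
  stopifnot(is(logo, "SequenceLogo"))
  logo@heights
}

#' Small-sample correction term e(n)
#'
#' `e(n) = (K - 1) / (2 ln(2) n)` bits, the expected overestimate of the
#' information content when a column's probabilities are estimated from n
#' sites over a K-letter alphabet.
#'
#' @param K Alphabet size.
#' @param n Number of sites.
#' @return Correction in bits.
#' @export
smallSampleCorrection <- function(K, n) (K - 1) / (2 * log(2) * n)

#' Build a sequence logo for one motif of a parsed MEME run
#'
#' Computes the logo from the parsed site sequences (so XML-only inputs
#' still yield logos). When the result also carries the file's printed
#' probability matrix, it is compared cell-wise against the site-derived
#' one and a consistency warning is emitted if any cell differs by more
#' than 0.01; the printed matrix is never used for drawing.
#'
#' @param result A [MemeResult-class].
#' @param motifId Motif id, e.g. `"motif_1"`.
#' @param smallSampleCorrection Passed to [informationContent()].
#' @param pseudocount Passed to [sitesToPPM()].
#' @return A [SequenceLogo-class].
#' @export
motifLogo <- function(result, motifId, smallSampleCorrection = FALSE,
                      pseudocount = 0) {
  stopifnot(is(result, "MemeResult"))
  if (!motifId %in% result@motifs$motif_id)
    .usageError("unknown motif id: ", motifId)
  sites <- result@occurrences$site_sequence[
    result@occurrences$motif_id == motifId]
  if (length(sites) == 0L)
    .usageError("motif ", motifId, " has no parsed sites to build a logo from")
  ppm <- sitesToPPM(sites, result@letters, pseudocount = pseudocount)
  printed <- result@ppms[[motifId]]
  if (!is.null(printed) && pseudocount == 0) {
    d <- abs(ppmMatrix(printed) - ppmMatrix(ppm))
    if (max(d) > 0.01)
      warning(sprintf(
        "printed probability matrix for %s disagrees with its sites (max |diff| = %.3f)",
        motifId, max(d)), call. = FALSE)
  }
  informationContent(ppm, smallSampleCorrection = smallSampleCorrection)
}

#' Render a sequence logo
#'
#' One letter stack per column; letters are drawn as filled polygons scaled
#' to their exact height in bits, stacked with the tallest letter on top.
#' The y-axis runs from 0 to `log2(K)` bits. Letters are colored by a
#' conventional chemistry palette (nucleotides by base; amino acids by
#' hydrophobic / polar / basic / acidic class).
#'
#' @param logo A [SequenceLogo-class], or a
#'   [PositionProbabilityMatrix-class] (information content is then
#'   computed with the correction off).
#' @param title Optional plot title.
#' @param minHeight Letters shorter than this (bits) are not drawn.
#' @return A `ggplot` object; write it with [saveFigure()].
#' @examples
#' ppm <- sitesToPPM(c("ACGT", "ACGT", "ACGA", "ACTT"), "DNA")
#' fig <- renderLogo(informationContent(ppm))
#' @export
renderLogo <- function(logo, title = NULL, minHeight = 1e-3) {
  if (is(logo, "PositionProbabilityMatrix")) logo <- informationContent(logo)
  stopifnot(is(logo, "SequenceLogo"))
  letters <- logo@ppm@alphabet
  K <- length(letters)
  W <- ncol(logo@heights)
  pal <- .logoPalette(letters)

  polys <- list()
  gid <- 0L
  for (j in seq_len(W)) {
    h <- logo@heights[, j]
    keep <- which(h >= minHeight)
    keep <- keep[order(h[keep])]           # ascending: tallest ends on top
    y0 <- 0
    for (k in keep) {
      gid <- gid + 1L
      g <- .letterPolygon(letters[k])
      g$x <- j - 0.45 + g$x * 0.9
      g$y <- y0 + g$y * h[k]
      g$group <- paste0(gid, ".", g$part)
      g$letter <- letters[k]
      polys[[gid]] <- g[, c("x", "y", "group", "letter")]
      y0 <- y0 + h[k]
    }
  }
  df <- if (length(polys)) do.call(rbind, polys)
        else data.frame(x = numeric(0), y = numeric(0),
                        group = character(0), letter = character(0))

  gg <- ggplot2::ggplot(df) +
    ggplot2::geom_polygon(ggplot2::aes(x = x, y = y, group = group,
                                       fill = letter)) +
    ggplot2::scale_fill_manual(values = pal, guide = "none") +
    ggplot2::scale_x_continuous(breaks = seq_len(W), limits = c(0.4, W + 0.6),
                                expand = c(0, 0)) +
    ggplot2::scale_y_continuous(limits = c(0, log2(K)), expand = c(0, 0)) +
    ggplot2::labs(x = "position", y = "bits", title = title) +
    ggplot2::theme_classic(base_size = 12) +
    ggplot2::theme(axis.line.x = ggplot2::element_blank())
  attr(gg, "logoLetterCount") <- gid
  gg
}

## Chemistry-based letter palette.
.logoPalette <- function(letters) {
  nuc <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839",
           U = "#D62839")
  if (all(letters %in% names(nuc))) return(nuc[letters])
  pal <- character(length(letters))
  names(pal) <- letters
  pal[letters %in% c("A", "V", "L", "I", "P", "W", "F", "M")] <- "#333333"
  pal[letters %in% c("G", "S", "T", "Y", "C", "Q", "N")] <- "#109648"
  pal[letters %in% c("K", "R", "H")] <- "#255C99"
  pal[letters %in% c("D", "E")] <- "#D62839"
  pal[pal == ""] <- "#888888"
  pal
}
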