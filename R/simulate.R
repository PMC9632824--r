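## Seeded generator of synthetic MEME runs with known planted ground truth.

#' Create a simulation spec for a synthetic MEME run
#'
#' The defaults emulate a ZOOPS protein-family scan: 10 motifs of widths
#' 4-7 discovered over 20 sequences, each motif planting at most one site
#' per sequence.
#'
#' @param seed Integer RNG seed.
#' @param alphabet `"DNA"`, `"RNA"` or `"PROTEIN"`.
#' @param nSequences Number of training sequences.
#' @param lengthRange Length-2 integer vector; sequence lengths are sampled
#'   uniformly in this range.
#' @param nMotifs Number of motifs to plant.
#' @param widthRange Length-2 integer vector of motif widths.
#' @param siteProb Per-sequence probability that a motif plants a site
#'   (ZOOPS: never more than one).
#' @param consensusProb Probability a site letter matches the consensus.
#' @param pValueRange Range for the log-uniform site p-value draw.
#' @return A [MotifSimSpec-class].
#' @examples
#' motifSimSpec(seed = 7, alphabet = "DNA", nSequences = 5)
#' @export
motifSimSpec <- function(seed = 1L, alphabet = "PROTEIN", nSequences = 20L,
                         lengthRange = c(100L, 500L), nMotifs = 10L,
                         widthRange = c(4L, 7L), siteProb = 0.6,
                         consensusProb = 0.75,
                         pValueRange = c(1e-12, 1e-2)) {
  new("MotifSimSpec", seed = as.integer(seed), alphabet = toupper(alphabet),
      nSequences = as.integer(nSequences),
      lengthRange = as.integer(lengthRange), nMotifs = as.integer(nMotifs),
      widthRange = as.integer(widthRange), siteProb = siteProb,
      consensusProb = consensusProb, pValueRange = pValueRange)
}

## Background frequencies quantized to 6 dp (the precision the writers
## print), last letter absorbing the remainder so the sum is exactly 1.
.simBackground <- function(letters) {
  K <- length(letters)
  b <- stats::runif(K, 0.5, 1.5)
  b <- round(b / sum(b), 6)
  b[K] <- 1 - sum(b[-K])
  names(b) <- letters
  b
}

## sample() treats a length-1 numeric x as 1:x; this never does
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.randLetters <- function(n, letters) {
  if (n <= 0L) return("")
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic MEME run with planted motif sites
#'
#' Deterministic for a fixed spec (including its seed). Sites are planted
#' ZOOPS-style (at most one site per sequence per motif, so same-motif
#' sites never overlap within a sequence), with letters drawn from a
#' degenerate-consensus model so the resulting logos are informative but
#' not trivial. Planted p-values are log-uniform in the spec's range and
#' rounded to the 3 significant digits the result files print; motif
#' e-values are nsites-scaled aggregates of the site p-values (format
#' realistic, not statistically faithful).
#'
#' @param spec A [MotifSimSpec-class].
#' @return A [MotifGroundTruth-class].
#' @examples
#' truth <- simulateMotifData(motifSimSpec(seed = 42))
#' truth
#' @export
simulateMotifData <- function(spec) {
  stopifnot(is(spec, "MotifSimSpec"))
  validObject(spec)
  letters <- .ALPHABETS[[spec@alphabet]]
  K <- length(letters)
  set.seed(spec@seed)

  lens <- .resample(seq(spec@lengthRange[1], spec@lengthRange[2]),
                    spec@nSequences, replace = TRUE)
  seqs <- data.frame(
    seq_id = sprintf("sequence_%d", seq_len(spec@nSequences) - 1L),
    name = sprintf("S%03d.%d", seq_len(spec@nSequences),
                   sample(1:2, spec@nSequences, replace = TRUE)),
    length = as.integer(lens),
    weight = rep(1, spec@nSequences),
    stringsAsFactors = FALSE)

  background <- .simBackground(letters)

  motifs <- data.frame(motif_id = character(0), name = character(0),
                       alt = character(0), width = integer(0),
                       nsites = integer(0), e_value = numeric(0),
                       bayes_threshold = numeric(0), stringsAsFactors = FALSE)
  occ <- .emptyOccurrences()

  if (spec@nMotifs > 0L) {
    widths <- .resample(seq(spec@widthRange[1], spec@widthRange[2]),
                        spec@nMotifs, replace = TRUE)
    for (m in seq_len(spec@nMotifs)) {
      w <- widths[m]
      consensus <- paste(sample(letters, w, replace = TRUE), collapse = "")
      consLetters <- strsplit(consensus, "")[[1]]
      plant <- stats::runif(spec@nSequences) < spec@siteProb
      rows <- list()
      for (s in which(plant)) {
        L <- seqs$length[s]
        start <- sample.int(L - w + 1L, 1L)
        site <- vapply(consLetters, function(cl) {
          if (stats::runif(1) < spec@consensusProb) cl
          else sample(setdiff(letters, cl), 1L)
        }, character(1))
        ## quantize through the printed format so the planted double is
        ## bit-identical to what parsing the report yields
        p <- as.numeric(sprintf("%.2e",
               10^stats::runif(1, log10(spec@pValueRange[1]),
                               log10(spec@pValueRange[2]))))
        strand <- if (spec@alphabet == "PROTEIN") "none"
                  else sample(c("+", "-"), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_name = seqs$name[s], sequence_length = L,
          motif_id = sprintf("motif_%d", m),
          start = start, end = start + w - 1L, strand = strand,
          p_value = p,
          site_sequence = paste(site, collapse = ""),
          left_flank = .randLetters(min(6L, start - 1L), letters),
          right_flank = .randLetters(min(6L, L - (start + w - 1L)), letters),
          stringsAsFactors = FALSE)
      }
      sites <- if (length(rows)) do.call(rbind, rows) else .emptyOccurrences()
      nsites <- nrow(sites)
      eval <- if (nsites > 0)
        exp(mean(log(sites$p_value))) * nsites * 1e3
      else 10^stats::runif(1, -2, 2)
      eval <- as.numeric(sprintf("%.1e", min(eval, 1e10)))
      motifs <- rbind(motifs, data.frame(
        motif_id = sprintf("motif_%d", m), name = consensus,
        alt = sprintf("MEME-%d", m), width = as.integer(w),
        nsites = as.integer(nsites), e_value = eval,
        bayes_threshold = as.numeric(sprintf("%.5f",
                                             stats::runif(1, 5, 12))),
        stringsAsFactors = FALSE))
      occ <- rbind(occ, sites)
    }
  }

  new("MotifGroundTruth", spec = spec, alphabet = spec@alphabet,
      letters = letters, background = background, version = "5.4.1",
      commandLine = sprintf(
        "meme sequences.fa %s -oc meme_out -mod zoops -nmotifs %d -minw %d -maxw %d -objfun classic -markov_order 0",
        switch(spec@alphabet, PROTEIN = "-protein", RNA = "-rna", "-dna"),
        spec@nMotifs, spec@widthRange[1], spec@widthRange[2]),
      sequences = seqs, motifs = motifs,
      occurrences = .orderOccurrences(occ))
}

## Site sequences of one motif, in canonical table order.
.truthSites <- function(truth, motifId) {
  occ <- truth@occurrences
  occ$site_sequence[occ$motif_id == motifId]
}

## PPM matrix a writer should print for a motif: estimated from the planted
## sites; one-hot consensus when the motif planted no site.
.truthPPMMatrix <- function(truth, motifId) {
  sites <- .truthSites(truth, motifId)
  m <- truth@motifs[truth@motifs$motif_id == motifId, ]
  if (length(sites) == 0L) {
    probs <- matrix(0, nrow = length(truth@letters), ncol = m$width,
                    dimnames = list(truth@letters, NULL))
    cons <- strsplit(m$name, "")[[1]]
    for (j in seq_along(cons)) probs[cons[j], j] <- 1
    return(probs)
  }
  ppmMatrix(sitesToPPM(sites, truth@letters))
}

#' Write a Newick tree over the simulated sequence names
#'
#' Generates a random rooted binary topology (via [ape::rtree()]) whose tip
#' labels are the truth's sequence names, optionally dropping `drop` of them
#' and adding `add` alien labels to exercise the intersection warnings of
#' the plotting path. Deterministic per seed.
#'
#' @param truth A [MotifGroundTruth-class].
#' @param path Output file path.
#' @param drop,add Number of sequence names to omit / alien tips to add.
#' @param seed Integer seed for the topology draw.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(truth, path, drop = 0L, add = 0L,
                        seed = truth@spec@seed) {
  labels <- truth@sequences$name
  set.seed(seed)
  if (drop > 0L) labels <- labels[-sample(seq_along(labels), drop)]
  if (add > 0L) labels <- c(labels, sprintf("alien_%02d", seq_len(add)))
  labels <- sample(labels)
  if (length(labels) < 2L)
    .usageError("a tree needs at least 2 tips; got ", length(labels))
  tree <- ape::rtree(length(labels), tip.label = labels)
  tree$edge.length <- round(tree$edge.length, 4)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a tip-annotation table for the simulated sequences
#'
#' TSV whose first column (`label`) holds the sequence names, plus a
#' two-level categorical `Group` column and a numeric `Domains` column —
#' the shape of the per-gene annotations drawn as tip points.
#'
#' @param truth A [MotifGroundTruth-class].
#' @param path Output file path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
writeTipAnnotations <- function(truth, path, seed = truth@spec@seed) {
  set.seed(seed + 1L)
  anno <- data.frame(
    label = truth@sequences$name,
    Group = sample(c("A", "B"), nrow(truth@sequences), replace = TRUE),
    Domains = sample(1:3, nrow(truth@sequences), replace = TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(anno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `meme.xml`, `meme.txt`, `tree.nwk`, `anno.tsv` and `truth.tsv`
#' (the planted occurrence table) into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [MotifSimSpec-class].
#' @param treeDrop,treeAdd Passed to [writeNewick()].
#' @return Named character vector of the file paths, invisibly; the
#'   [MotifGroundTruth-class] is attached as attribute `"truth"`.
#' @examples
#' d <- file.path(tempdir(), "simdemo")
#' files <- simulateMemeDataset(d, motifSimSpec(seed = 3, nSequences = 6))
#' basename(unname(files))
#' @export
simulateMemeDataset <- function(dir, spec = motifSimSpec(),
                                treeDrop = 0L, treeAdd = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulateMotifData(spec)
  paths <- c(xml = file.path(dir, "meme.xml"),
             txt = file.path(dir, "meme.txt"),
             tree = file.path(dir, "tree.nwk"),
             anno = file.path(dir, "anno.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeMemeXML(truth, paths[["xml"]])
  writeMemeText(truth, paths[["txt"]])
  if (nrow(truth@sequences) + treeAdd - treeDrop >= 2L) {
    writeNewick(truth, paths[["tree"]], drop = treeDrop, add = treeAdd)
  } else {
    paths <- paths[names(paths) != "tree"]  # a tree needs >= 2 tips
  }
  writeTipAnnotations(truth, paths[["anno"]])
  writeOccurrenceTSV(occurrenceTable(truth), paths[["truth"]])
  attr(paths, "truth") <- truth
  invisible(paths)
}
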