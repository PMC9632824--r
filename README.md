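# motifscape

Motif discovery with the MEME suite ends with three files — an `.html`
report, an `.xml` results document and a plain-text `.txt` report. The HTML
is pleasant to look at but cannot be recombined into publication figures,
and the XML/text files are hard to read and do not plug into the R
phylogenetics/plotting ecosystem. Widely used Bioconductor importers read
the text dialect but drop the one thing gene-family studies need most:
**where each motif sits on each input sequence**.

`motifscape` closes that gap for anyone characterizing a gene or protein
family (for example a plant transcription-factor family scanned with
`meme -protein -mod zoops -nmotifs 10 -minw 4 -maxw 7`). It

* parses **both** MEME 5.x result dialects (`.xml` and `.txt`) into one
  normalized, filterable occurrence table with 1-based inclusive
  coordinates (`end − start + 1 = width`);
* draws **motif-location maps** — one track per sequence, one colored box
  per occurrence — optionally row-ordered by and drawn beside a **Newick
  phylogeny** with tip-annotation points;
* computes **position probability matrices** and **sequence logos** from
  the extracted site sequences, with per-column information content
  `R_i = log2(K) − H_i − e(n)` where `H_i = −Σ_k p_ik log2 p_ik` and the
  optional small-sample correction `e(n) = (K−1)/(2 ln 2 · n)`; letter
  heights are `p_ik · R_i`;
* ships a seeded **synthetic-data generator** that writes MEME-style
  XML/text files, trees and annotation tables with known planted ground
  truth, so the whole pipeline is testable without running MEME;
* exposes everything from the shell via `motifCLI()` /
  `inst/cli/motifscape` (`extract`, `plot-locations`, `plot-logo`,
  `simulate`).

## Worked example

```r
library(motifscape)

## a complete synthetic MEME run with known planted sites
d <- file.path(tempdir(), "demo")
files <- simulateMemeDataset(d, motifSimSpec(seed = 20))

res <- parseMemeXML(files[["xml"]])
res
#> MemeResult (MEME 5.4.1, PROTEIN)
#>   20 sequences, 10 motifs, 112 occurrences
#>   + scanned-sites summary with 112 entries

tab <- occurrenceTable(res)
head(tab, 3)
#>   sequence_name sequence_length motif_id start end strand  p_value
#> 1        S001.2             265 motif_10    19  23   none 2.12e-11
#> 2        S001.2             265  motif_5    60  65   none 1.72e-12
#> 3        S001.2             265  motif_6   250 254   none 2.24e-06
#>   site_sequence left_flank right_flank
#> 1         NVFMT     ICNCLR      WNEMHL
#> 2        DNFDVY     RQYNNL      VTSPYY
#> 3         TEENS     PRDHCC      WSMFFS

nrow(filterOccurrences(tab, maxP = 1e-6))   # site-level significance filter
#> [1] 65

## tree-ordered location map with tip annotations (Fig-style two panels)
fig <- plotMotifLocations(tab, tree = files[["tree"]],
                          annotations = files[["anno"]])
saveFigure(fig, file.path(d, "locations.svg"))

## sequence logo for one motif, from its extracted site sequences
logo <- motifLogo(res, "motif_1")
logo
#> SequenceLogo: 5 columns, total IC 16.01 bits (correction off)
round(logoIC(logo), 3)
#> [1] 3.672 3.070 3.672 3.070 2.529
saveFigure(renderLogo(logo, title = "motif_1"),
           file.path(d, "logo.svg"), width = 5, height = 3)
```

Each row of the occurrence table is one contributing site: the sequence it
sits on (with that sequence's total length, so the table alone suffices for
plotting), the motif, the 1-based inclusive start/end, the strand (`+`/`-`
for nucleotide runs, `none` for protein), MEME's site p-value, and the site
sequence with its flanks. The `logoIC` values are per-column information
content in bits (max `log2(20) ≈ 4.32` for proteins).

The same flow from a shell:

```sh
Rscript inst/cli/motifscape simulate --seed 20 -o demo/
Rscript inst/cli/motifscape extract demo/meme.xml -o demo/out.tsv
Rscript inst/cli/motifscape plot-locations demo/out.tsv \
    --tree demo/tree.nwk --anno demo/anno.tsv -o demo/fig.svg
```

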