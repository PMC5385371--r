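Package: vbcode
Title: Variation-Block InDel Barcodes for Cultivar Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and analysing DNA barcode panels anchored in
    dense variation blocks (dVBs). Segments chromosomes into dense and sparse
    variation blocks from per-cultivar variant calls, assigns shared block
    types across cultivars by SNV concordance, extracts dVB-specific InDel
    marker candidates under gel-resolvable length and amplicon-size filters,
    scores markers by polymorphism information content (PIC), encodes cultivar
    genotypes as binary barcodes relative to a reference genome, and performs
    panel-level analyses: simple-matching distances, neighbor-joining
    clustering, minimal discriminating marker sets, closest-match and
    pedigree/backcross consistency checks, and heterozygosity (fixation)
    reports. Includes a mosaic-genome cross simulator with block-dependent
    recombination rates so the whole pipeline is testable on synthetic panels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
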