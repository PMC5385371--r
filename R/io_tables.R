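#' Write variation blocks to BED
#'
#' Internal coordinates are 1-based inclusive (the VCF convention); this
#' writer is the single point of translation to BED's 0-based half-open
#' intervals. The name column carries the block class (and type label for
#' typed dense blocks, e.g. `"dvb:3"`), the score column the variant density
#' in variants/kb.
#'
#' @param blocks A data.frame of blocks (`chrom`, `start`, `end`, `klass`,
#'   optionally `cultivar`, `density`, `type_label`).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_blocks_bed <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  if (nrow(blocks) == 0) return(invisible(path))
  key <- if ("cultivar" %in% names(blocks)) {
    paste(blocks$cultivar, blocks$chrom)
  } else blocks$chrom
  for (k in unique(key)) {
    b <- blocks[key == k, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("overlapping blocks on ", k)
    }
  }
  name <- blocks$klass
  if ("type_label" %in% names(blocks)) {
    typed <- !is.na(blocks$type_label)
    name[typed] <- paste0(name[typed], ":", blocks$type_label[typed])
  }
  score <- if ("density" %in% names(blocks)) round(blocks$density, 4) else 0
  out <- data.frame(blocks$chrom, blocks$start - 1L, blocks$end, name, score)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and parse Newick trees
#'
#' `write_newick()` serialises a phylogeny (an [ape] `phylo` object, or a
#' single leaf label) as Newick; `parse_newick()` reads it back. Round trips
#' preserve topology and branch lengths.
#'
#' @param tree A `phylo` object, or a length-1 character vector for a
#'   single-leaf tree.
#' @param path File path.
#' @return `parse_newick()` returns a `phylo` object (or a leaf label for
#'   single-leaf files); `write_newick()` returns the path invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.character(tree) && length(tree) == 1) {
    writeLines(paste0(tree, ":0.0;"), path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' @rdname write_newick
#' @export
parse_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # single-leaf newick is not a valid phylo; return the label
  if (!grepl("(", txt, fixed = TRUE)) {
    return(sub(":.*$", "", sub(";.*$", "", txt)))
  }
  ape::read.tree(text = txt)
}

#' Genotype tables
#'
#' A genotype table holds band-pattern calls for a marker panel: per marker
#' and cultivar, the observed allele pattern label (for gel-style markers the
#' expected amplicon length in bp), `"x/y"` for a heterozygous call showing
#' two patterns, or `"."` for missing.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `dvb`, and
#'   optionally `ref_pattern` (the reference genome's pattern at the marker).
#' @param cultivars Character vector of cultivar ids.
#' @param calls Character matrix, cultivars x markers.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(markers, cultivars, calls) {
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos", "dvb") %in% names(markers)),
            !anyDuplicated(markers$id), !anyDuplicated(cultivars),
            nrow(calls) == length(cultivars),
            ncol(calls) == nrow(markers))
  dimnames(calls) <- list(cultivars, markers$id)
  structure(list(markers = markers, cultivars = cultivars, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$cultivars), "cultivars x",
      nrow(x$markers), "markers\n")
  miss <- mean(x$calls == ".")
  cat(sprintf("  missing: %.1f%%  heterozygous: %.1f%%\n",
              100 * miss, 100 * mean(grepl("/", x$calls))))
  invisible(x)
}

#' Serialise a genotype table as TSV
#'
#' Layout: comment lines carrying marker metadata (`#chrom`, `#pos`, and
#' `#ref_pattern` when present), then a two-line header (marker id, dVB id),
#' then one row per cultivar. Missing cells are `"."`.
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return Invisibly, the path. `read_genotype_table()` returns the
#'   `genotype_table`.
#' @export
write_genotype_table <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- gt$markers
  writeLines(paste(c("#chrom", m$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", m$pos), collapse = "\t"), con)
  if ("ref_pattern" %in% names(m)) {
    writeLines(paste(c("#ref_pattern", m$ref_pattern), collapse = "\t"), con)
  }
  writeLines(paste(c("marker", m$id), collapse = "\t"), con)
  writeLines(paste(c("dvb", m$dvb), collapse = "\t"), con)
  for (i in seq_along(gt$cultivars)) {
    writeLines(paste(c(gt$cultivars[i], gt$calls[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  meta <- list()
  i <- 1
  while (startsWith(lines[i], "#")) {
    meta[[sub("^#", "", fields[[i]][1])]] <- fields[[i]][-1]
    i <- i + 1
  }
  stopifnot(fields[[i]][1] == "marker", fields[[i + 1]][1] == "dvb")
  ids <- fields[[i]][-1]
  dvb <- fields[[i + 1]][-1]
  body <- fields[seq(i + 2, length(fields))]
  cultivars <- vapply(body, `[`, character(1), 1)
  calls <- t(vapply(body, function(f) f[-1], character(length(ids))))
  markers <- data.frame(id = ids,
                        chrom = if (!is.null(meta$chrom)) meta$chrom else NA,
                        pos = if (!is.null(meta$pos)) as.integer(meta$pos) else NA,
                        dvb = dvb, stringsAsFactors = FALSE)
  if (!is.null(meta$ref_pattern)) markers$ref_pattern <- meta$ref_pattern
  genotype_table(markers, cultivars, calls)
}
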