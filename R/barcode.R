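#' Encode a genotype table as a barcode matrix
#'
#' Recodes every call relative to a reference cultivar: `"a"` when the
#' pattern equals the reference's pattern at that marker, `"b"` for the most
#' common alternative pattern in the panel, `"c"` for any further (third)
#' pattern, `"h"` for a heterozygous call showing two distinct patterns, and
#' `"."` for missing. Markers are ordered genomically (chromosome, then
#' position), so a cultivar's row read left to right is its barcode.
#'
#' When the reference cultivar's own call is missing at a marker, the column
#' is keyed to the declared reference-genome pattern (`ref_pattern` in the
#' marker table) with a warning.
#'
#' @param gt A [genotype_table()].
#' @param reference Reference cultivar id (must be a row of `gt`).
#' @return A `barcode_matrix`: character matrix (cultivars x markers) over
#'   `{a, b, c, h, .}` with attributes `markers`, `reference` and `checksum`
#'   (panel fingerprint preventing cross-panel comparison).
#' @export
encode_genotypes <- function(gt, reference) {
  if (!reference %in% gt$cultivars) stop("reference cultivar not in table")
  ord <- order(gt$markers$chrom, gt$markers$pos)
  markers <- gt$markers[ord, , drop = FALSE]
  calls <- gt$calls[, ord, drop = FALSE]
  n_cv <- length(gt$cultivars)
  codes <- matrix(".", n_cv, nrow(markers),
                  dimnames = list(gt$cultivars, markers$id))
  ref_row <- match(reference, gt$cultivars)
  for (j in seq_len(nrow(markers))) {
    cj <- calls[, j]
    ref_pat <- cj[ref_row]
    if (ref_pat == "." || grepl("/", ref_pat)) {
      if (is.null(markers$ref_pattern)) {
        stop("reference call missing at ", markers$id[j],
             " and no declared ref_pattern")
      }
      ref_pat <- markers$ref_pattern[j]
      warning("reference call missing at ", markers$id[j],
              "; keyed to declared reference pattern")
    }
    hom <- cj[cj != "." & !grepl("/", cj)]
    alt_tab <- sort(table(hom[hom != ref_pat]), decreasing = TRUE)
    alt_rank <- setNames(seq_along(alt_tab), names(alt_tab))
    for (i in seq_len(n_cv)) {
      v <- cj[i]
      if (v == ".") next
      if (grepl("/", v)) {
        codes[i, j] <- "h"
      } else if (v == ref_pat) {
        codes[i, j] <- "a"
      } else {
        r <- alt_rank[[v]]
        if (is.null(r)) r <- length(alt_rank) + 1  # pattern seen only in hets
        codes[i, j] <- if (r == 1) "b" else "c"
      }
    }
  }
  structure(codes, class = "barcode_matrix", markers = markers,
            reference = reference, checksum = panel_checksum(markers$id))
}

#' Panel checksum
#'
#' Deterministic fingerprint of an ordered marker-id list, used to refuse
#' comparison of barcodes produced from different panels.
#'
#' @param marker_ids Ordered character vector of marker ids.
#' @return An 8-character hex string.
#' @export
panel_checksum <- function(marker_ids) {
  s <- utf8ToInt(paste(marker_ids, collapse = "|"))
  h <- 5381
  for (c in s) h <- (h * 33 + c) %% 2147483647  # djb2 mod Mersenne prime
  sprintf("%08x", as.integer(h))
}

#' @export
print.barcode_matrix <- function(x, ...) {
  cat("barcode_matrix:", nrow(x), "cultivars x", ncol(x),
      "markers (reference:", attr(x, "reference"),
      "; panel", attr(x, "checksum"), ")\n")
  tab <- table(factor(x, levels = c("a", "b", "c", "h", ".")))
  cat("  codes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Compact text serialisation of one barcode row
#'
#' `barcode_string()` renders a cultivar's codes as
#' `"<checksum>|<codes>"`; `parse_barcode()` inverts it. The checksum makes
#' codes from different marker panels refuse silent comparison.
#'
#' @param bm A `barcode_matrix`.
#' @param cultivar Cultivar id.
#' @return `barcode_string()`: a character scalar. `parse_barcode()`: a
#'   character vector of codes with attribute `checksum`.
#' @export
barcode_string <- function(bm, cultivar) {
  paste0(attr(bm, "checksum"), "|",
         paste(bm[cultivar, ], collapse = ""))
}

#' @rdname barcode_string
#' @param text A string produced by `barcode_string()`.
#' @param panel Optional `barcode_matrix` (or checksum string) the parsed
#'   code must belong to; a mismatch is an error.
#' @export
parse_barcode <- function(text, panel = NULL) {
  if (!nzchar(text)) stop("empty barcode string")
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[2])) stop("malformed barcode string")
  if (!is.null(panel)) {
    want <- if (inherits(panel, "barcode_matrix")) attr(panel, "checksum")
            else panel
    if (parts[1] != want) stop("panel mismatch")
  }
  structure(strsplit(parts[2], "")[[1]], checksum = parts[1])
}

#' Serialise a barcode matrix as TSV
#'
#' @param bm A `barcode_matrix`.
#' @param path Output path.
#' @return Invisibly, the path; `read_barcode_matrix()` returns the matrix.
#' @export
write_barcode_matrix <- function(bm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- attr(bm, "markers")
  writeLines(paste0("#reference\t", attr(bm, "reference")), con)
  writeLines(paste0("#checksum\t", attr(bm, "checksum")), con)
  writeLines(paste(c("#chrom", m$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", m$pos), collapse = "\t"), con)
  writeLines(paste(c("#dvb", m$dvb), collapse = "\t"), con)
  writeLines(paste(c("cultivar", colnames(bm)), collapse = "\t"), con)
  for (i in seq_len(nrow(bm))) {
    writeLines(paste(c(rownames(bm)[i], bm[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_barcode_matrix
#' @export
read_barcode_matrix <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  meta <- list()
  i <- 1
  while (startsWith(lines[i], "#")) {
    meta[[sub("^#", "", fields[[i]][1])]] <- fields[[i]][-1]
    i <- i + 1
  }
  ids <- fields[[i]][-1]
  body <- fields[seq(i + 1, length(fields))]
  cultivars <- vapply(body, `[`, character(1), 1)
  codes <- t(vapply(body, function(f) f[-1], character(length(ids))))
  dimnames(codes) <- list(cultivars, ids)
  markers <- data.frame(id = ids, chrom = meta$chrom,
                        pos = as.integer(meta$pos), dvb = meta$dvb,
                        stringsAsFactors = FALSE)
  structure(codes, class = "barcode_matrix", markers = markers,
            reference = meta$reference, checksum = meta$checksum)
}
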