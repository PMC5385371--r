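#' Render a cultivar's barcode
#'
#' 1D style draws one stripe per marker in genomic order (white = `a`, same
#' as reference; black = `b`, different). 2D style wraps the markers into a
#' grid with one row per chromosome, padding trailing cells grey.
#' Heterozygous calls render green, third alleles orange, missing light
#' grey. The returned object embeds the layout (per-row marker counts and
#' cell geometry), so a rendered barcode — including its pixel raster — can
#' be decoded back to the code string with [decode_barcode()].
#'
#' @param bm A `barcode_matrix`.
#' @param cultivar Cultivar id (row of `bm`).
#' @param style `"1d"` or `"2d"`.
#' @param palette Named colours for codes `a`, `b`, `c`, `h`, `.`, and `pad`.
#' @param cell_px Cell size in pixels for the raster.
#' @return A `barcode_render` object: codes, layout, palette and an RGB
#'   raster array (rows x cols x 3, values in \[0, 1\]).
#' @export
render_barcode <- function(bm, cultivar, style = c("1d", "2d"),
                           palette = c(a = "white", b = "black",
                                       c = "orange", h = "green3",
                                       "." = "grey70", pad = "grey40"),
                           cell_px = 8L) {
  style <- match.arg(style)
  codes <- bm[cultivar, ]
  chroms <- attr(bm, "markers")$chrom
  if (style == "1d") {
    rows <- list(seq_along(codes))
    row_names <- "all"
  } else {
    row_names <- unique(chroms)
    rows <- lapply(row_names, function(ch) which(chroms == ch))
  }
  width <- max(lengths(rows))
  grid <- matrix("pad", nrow = length(rows), ncol = width)
  for (r in seq_along(rows)) grid[r, seq_along(rows[[r]])] <- codes[rows[[r]]]
  rgb <- t(col2rgb(palette) / 255)
  raster <- array(0, dim = c(nrow(grid) * cell_px, width * cell_px, 3))
  for (r in seq_len(nrow(grid))) for (cc in seq_len(width)) {
    px <- rgb[match(grid[r, cc], names(palette)), ]
    raster[(r - 1) * cell_px + seq_len(cell_px),
           (cc - 1) * cell_px + seq_len(cell_px), ] <-
      rep(px, each = cell_px * cell_px)
  }
  structure(list(cultivar = cultivar, style = style,
                 codes = paste(codes, collapse = ""),
                 row_names = row_names, n_per_row = lengths(rows),
                 cell_px = cell_px, palette = palette, raster = raster),
            class = "barcode_render")
}

#' Decode a rendered barcode back to its code string
#'
#' Samples the centre pixel of every cell of the raster and inverts the
#' palette, using the embedded layout (per-row marker counts, cell size) to
#' skip padding.
#'
#' @param render A `barcode_render` object.
#' @return The code string over `{a, b, c, h, .}`.
#' @export
decode_barcode <- function(render) {
  rgb <- t(col2rgb(render$palette) / 255)
  half <- ceiling(render$cell_px / 2)
  out <- character(0)
  for (r in seq_along(render$n_per_row)) {
    for (cc in seq_len(render$n_per_row[r])) {
      px <- render$raster[(r - 1) * render$cell_px + half,
                          (cc - 1) * render$cell_px + half, ]
      d <- colSums((t(rgb) - px)^2)
      out <- c(out, names(render$palette)[which.min(d)])
    }
  }
  paste(out, collapse = "")
}

#' Write a rendered barcode as PNG, or print it as ASCII art
#'
#' @param render A `barcode_render` object.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_barcode_png <- function(render, path) {
  png::writePNG(render$raster, target = path)
  invisible(path)
}

#' @export
print.barcode_render <- function(x, ...) {
  glyph <- c(a = ".", b = "#", c = "o", h = "+", "." = " ")
  cat("barcode (", x$cultivar, ", ", x$style, "):\n", sep = "")
  codes <- strsplit(x$codes, "")[[1]]
  at <- 1
  for (r in seq_along(x$n_per_row)) {
    seg <- codes[seq(at, length.out = x$n_per_row[r])]
    cat(sprintf("  %-6s|%s|\n", x$row_names[r],
                paste(glyph[seg], collapse = "")))
    at <- at + x$n_per_row[r]
  }
  invisible(x)
}
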