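mk_gt <- function(calls, cultivars, ref_pattern = NULL) {
  n <- ncol(calls)
  markers <- data.frame(id = sprintf("m%d", seq_len(n)), chrom = "chr1",
                        pos = seq_len(n) * 100L, dvb = as.character(seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(ref_pattern)) markers$ref_pattern <- ref_pattern
  genotype_table(markers, cultivars, calls)
}

test_that("encoding keys every cell to the reference cultivar", {
  calls <- rbind(REF = c("100", "95", "80"),
                 X   = c("100", "88", "80"),
                 Y   = c("95", "95", "100/80"),
                 Z   = c(".", "88", "80"))
  bm <- encode_genotypes(mk_gt(calls, rownames(calls)), "REF")
  expect_equal(unname(bm["REF", ]), c("a", "a", "a"))
  expect_equal(unname(bm["X", ]), c("a", "b", "a"))
  expect_equal(unname(bm["Y", ]), c("b", "a", "h"))
  expect_equal(unname(bm["Z", ]), c(".", "b", "a"))
})

test_that("a cultivar differing at 2 of 202 markers gets exactly two b codes", {
  calls <- matrix("100", 2, 202, dimnames = list(c("REF", "Q"), NULL))
  calls["Q", c(17, 171)] <- "88"
  bm <- encode_genotypes(mk_gt(calls, c("REF", "Q")), "REF")
  expect_equal(sum(bm["Q", ] == "b"), 2)
  expect_equal(sum(bm["Q", ] == "a"), 200)
})

test_that("third alleles code c, ranked below the most common alternative", {
  calls <- rbind(REF = "100", A = "88", B = "88", C = "95")
  bm <- encode_genotypes(mk_gt(calls, rownames(calls)), "REF")
  expect_equal(unname(bm[, 1]), c("a", "b", "b", "c"))
})

test_that("a missing reference call falls back to the declared pattern", {
  calls <- rbind(REF = ".", X = "100", Y = "88")
  gt <- mk_gt(calls, rownames(calls), ref_pattern = "100")
  expect_warning(bm <- encode_genotypes(gt, "REF"), "declared")
  expect_equal(unname(bm["X", ]), "a")
  expect_equal(unname(bm["Y", ]), "b")
  expect_error(suppressWarnings(
    encode_genotypes(mk_gt(calls, rownames(calls)), "REF")), "ref_pattern")
})

test_that("swapping the reference swaps a and b at biallelic markers", {
  calls <- rbind(R1 = c("100", "95"), R2 = c("88", "95"),
                 X = c("100", "80"), Y = c("88", "80"))
  gt <- mk_gt(calls, rownames(calls))
  bm1 <- encode_genotypes(gt, "R1")
  bm2 <- encode_genotypes(gt, "R2")
  swap <- c(a = "b", b = "a", c = "c", h = "h", "." = ".")
  # marker 1: R1 and R2 carry the two patterns -> codes swap roles
  expect_equal(unname(swap[bm1[, 1]]), unname(bm2[, 1]))
  # encoding is idempotent for a fixed reference
  expect_identical(unclass(encode_genotypes(gt, "R1")), unclass(bm1))
})

test_that("barcode strings round-trip and refuse cross-panel comparison", {
  bm <- bm_from_codes(matrix(c("a", "a", "b", ".", "h",
                               "b", "a", "a", "a", "a"), 2, 5, byrow = TRUE,
                             dimnames = list(c("X", "Y"), NULL)))
  s <- barcode_string(bm, "X")
  row <- parse_barcode(s, bm)
  expect_equal(unclass(row), c("a", "a", "b", ".", "h"), ignore_attr = TRUE)
  other <- bm_from_codes(matrix("a", 1, 4,
                                dimnames = list("Z", paste0("k", 1:4))))
  expect_error(parse_barcode(s, other), "panel mismatch")
  expect_error(parse_barcode(""), "empty")
  r1 <- parse_barcode(barcode_string(bm, "X"))
  r2 <- parse_barcode(barcode_string(other, "Z"))
  expect_error(pairwise_difference(r1, r2), "panel mismatch")
})

test_that("1D rendering maps codes to stripes that decode back", {
  bm <- bm_from_codes(matrix(rep("a", 202), 1,
                             dimnames = list("W", NULL)))
  r <- render_barcode(bm, "W", style = "1d")
  expect_equal(dim(r$raster)[2], 202 * r$cell_px)
  expect_true(all(r$raster == 1))  # all white
  expect_equal(decode_barcode(r), strrep("a", 202))

  ab <- bm_from_codes(matrix(c("a", "b"), 1, 2, dimnames = list("W", NULL)))
  r <- render_barcode(ab, "W", style = "1d")
  expect_equal(r$raster[1, 1, ], c(1, 1, 1))                    # white first
  expect_equal(r$raster[1, dim(r$raster)[2], ], c(0, 0, 0))     # then black
})

test_that("2D rendering wraps by chromosome and round-trips via PNG", {
  set.seed(5)
  codes <- matrix(sample(c("a", "b", "c", "h", "."), 30, replace = TRUE,
                         prob = c(.5, .3, .05, .1, .05)), 1, 30,
                  dimnames = list("Q", NULL))
  bm <- bm_from_codes(codes, chrom = rep(c("chr1", "chr2", "chr3"), c(12, 10, 8)))
  r <- render_barcode(bm, "Q", style = "2d")
  expect_equal(r$n_per_row, c(12, 10, 8), ignore_attr = TRUE)
  expect_equal(dim(r$raster)[1], 3 * r$cell_px)
  expect_equal(decode_barcode(r), paste(codes, collapse = ""))
  # write to PNG, read the pixels back, decode from the file's raster
  tmp <- withr::local_tempfile(fileext = ".png")
  write_barcode_png(r, tmp)
  r2 <- r
  r2$raster <- png::readPNG(tmp)
  expect_equal(decode_barcode(r2), paste(codes, collapse = ""))
})
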