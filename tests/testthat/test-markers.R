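test_that("candidate extraction keeps 5-20 bp InDels inside dense blocks", {
  vt <- read_vcf(fixture_vcf())
  cand <- extract_candidate_indels(vt, fixture_blocks())
  expect_setequal(cand$pos, c(52000, 53000, 54000))
  expect_setequal(cand$indel_size, c(5L, 12L, 20L))
  # neither the 3 bp nor the 25 bp in-dVB InDel, nor any out-of-dVB InDel,
  # nor the SNV survives
  expect_false(any(cand$pos %in% c(51000, 55000, 56000)))
  expect_false(any(cand$pos < 50000))
})

test_that("amplicon filter keeps candidates with all alleles in range", {
  r <- amplicon_filter(c(13, 1), 40, 40)
  expect_true(r$keep)
  expect_equal(r$sizes, c(93, 81))
  expect_false(amplicon_filter(c(45, 1), 40, 40)$keep)  # 125 > 120
  expect_false(amplicon_filter(c(13, 1), 30, 30)$keep)  # 61 < 80
  # boundaries are inclusive
  expect_true(amplicon_filter(c(40, 0), 40, 40)$keep)   # 120 and 80
  expect_error(amplicon_filter(c(13, 1), 0, 40))
})

test_that("default flanks centre the reference amplicon on the target", {
  fl <- default_flanks(13, 100)
  expect_equal(sum(fl) + 13, 100)
  expect_lte(abs(fl[1] - fl[2]), 1)
})

test_that("PIC matches the defining formula on worked examples", {
  expect_equal(round(pic(c(4, 143)), 2), 0.05)
  expect_equal(round(pic(c(76, 71)), 2), 0.50)
  expect_equal(pic(c(147, 0)), 0)
  expect_equal(pic(c(50, 50)), 0.5)
  expect_error(pic(c(0, 0)), "zero")
  expect_error(pic(c(-1, 5)))
})

test_that("PIC is permutation- and scale-invariant and equals 1 - homozygosity", {
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    counts <- sample.int(50, k, replace = TRUE)
    expect_equal(pic(counts), pic(sample(counts)))
    expect_equal(pic(counts), pic(counts * 7))
    expect_lte(pic(counts), 1 - 1 / k)
    # independent tally oracle: expand to calls, tabulate frequencies
    calls <- rep(letters[seq_len(k)], counts)
    freq <- as.numeric(table(calls)) / length(calls)
    expect_equal(pic(counts), 1 - sum(freq^2))
  }
})

test_that("marker_stats drops missing calls and counts patterns", {
  s <- marker_stats(c("100", "100", "95", ".", "100/95"))
  expect_equal(s$n_scored, 4)
  expect_equal(s$missing_frac, 0.2)
  expect_equal(s$n_patterns, 3)  # het composite is its own band pattern
  expect_equal(s$pic, 1 - sum((c(2, 1, 1) / 4)^2))
})

mini_panel <- function(calls_by_marker, dvb, pos = NULL, ref_len = NULL,
                       alt_lens = NULL) {
  n <- length(calls_by_marker)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref_len)) ref_len <- rep(13L, n)
  if (is.null(alt_lens)) alt_lens <- rep("1", n)
  cand <- data.frame(id = sprintf("m%d", seq_len(n)), chrom = "chr1",
                     pos = pos, ref_len = ref_len, alt_lens = alt_lens,
                     indel_size = 12L, dvb = dvb, stringsAsFactors = FALSE)
  class(cand) <- c("indel_candidates", "data.frame")
  cultivars <- sprintf("cv%d", seq_along(calls_by_marker[[1]]))
  calls <- do.call(cbind, calls_by_marker)
  gt <- genotype_table(
    data.frame(id = cand$id, chrom = cand$chrom, pos = cand$pos,
               dvb = cand$dvb, stringsAsFactors = FALSE),
    cultivars, calls)
  list(cand = cand, gt = gt)
}

test_that("marker selection ranks by PIC, then size difference, then position", {
  # same dVB: PIC 0.42 pattern (70/30) beats 0.30 pattern (81/19)
  p <- mini_panel(list(c(rep("100", 70), rep("88", 30)),
                       c(rep("100", 81), rep("88", 19))), dvb = c("1", "1"))
  sel <- select_markers(p$cand, p$gt)
  expect_equal(sel$id, "m1")
  expect_equal(round(sel$pic, 2), 0.42)

  # PIC tie -> larger allele-size difference wins
  p <- mini_panel(list(c(rep("100", 5), rep("95", 5)),
                       c(rep("100", 5), rep("88", 5))),
                  dvb = c("1", "1"), ref_len = c(13L, 13L),
                  alt_lens = c("8", "1"))
  sel <- select_markers(p$cand, p$gt)
  expect_equal(sel$id, "m2")

  # full tie -> smaller position wins
  p <- mini_panel(list(c(rep("100", 5), rep("88", 5)),
                       c(rep("100", 5), rep("88", 5))),
                  dvb = c("1", "1"), pos = c(500L, 200L))
  sel <- select_markers(p$cand, p$gt)
  expect_equal(sel$pos, 200L)
})

test_that("selection respects the per-dVB quota and reports uncovered dVBs", {
  # dvb 2's only candidate fails the amplicon filter (25 bp insertion)
  p <- mini_panel(list(c(rep("100", 5), rep("88", 5)),
                       c(rep("100", 5), rep("88", 5)),
                       c(rep("100", 5), rep("125", 5))),
                  dvb = c("1", "1", "2"),
                  ref_len = c(13L, 13L, 1L), alt_lens = c("1", "1", "26"))
  sel <- select_markers(p$cand, p$gt)
  expect_equal(nrow(sel), 1)
  expect_equal(attr(sel, "uncovered_dvbs"), "2")

  # missingness above the cap disqualifies a candidate
  calls <- c(rep("100", 4), rep("88", 2), rep(".", 4))
  p <- mini_panel(list(calls), dvb = "1")
  sel <- select_markers(p$cand, p$gt, max_missing = 0.1)
  expect_equal(nrow(sel), 0)
  expect_equal(attr(sel, "uncovered_dvbs"), "1")
})

test_that("selection is stable under candidate order shuffling", {
  set.seed(9)
  calls <- list(c(rep("100", 6), rep("88", 4)),
                c(rep("100", 3), rep("88", 7)),
                c(rep("100", 5), rep("88", 5)))
  p <- mini_panel(calls, dvb = c("1", "1", "1"))
  ref_sel <- select_markers(p$cand, p$gt)
  perm <- sample(3)
  cand2 <- p$cand[perm, ]
  gt2 <- genotype_table(p$gt$markers[perm, ], p$gt$cultivars,
                        p$gt$calls[, perm])
  expect_equal(select_markers(cand2, gt2)$id, ref_sel$id)
})
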