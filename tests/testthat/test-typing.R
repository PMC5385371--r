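test_that("SNV concordance is the Jaccard index of variant keys", {
  expect_equal(snv_concordance(c("1:A", "2:T"), c("1:A", "2:T")), 1.0)
  expect_equal(snv_concordance(c("1:A"), c("2:T")), 0.0)
  expect_equal(snv_concordance(character(0), character(0)), 1.0)
  # 8 shared, 1 private each side: union 10 -> exactly the 0.8 boundary
  a <- c(paste0(1:8, ":A"), "9:A")
  b <- c(paste0(1:8, ":A"), "10:T")
  expect_equal(snv_concordance(a, b), 0.8)
})

mk_blocks <- function(cultivars, start = 1000, end = 21000) {
  data.frame(chrom = "chr1", start = start, end = end, klass = "dvb",
             cultivar = cultivars, density = 5,
             type_label = NA_integer_, stringsAsFactors = FALSE)
}

keyset <- function(pos, allele = "A") paste("chr1", pos, allele, sep = ":")

test_that("identical overlapping blocks share a type label", {
  blocks <- mk_blocks(c("A", "B"))
  keys <- list(A = keyset(seq(1100, 20900, by = 200)),
               B = keyset(seq(1100, 20900, by = 200)))
  out <- assign_block_types(blocks, keys)
  expect_equal(out$type_label[1], out$type_label[2])
})

test_that("the 0.8 concordance threshold is inclusive", {
  blocks <- mk_blocks(c("A", "B"))
  shared <- keyset(seq(2000, 17800, by = 200))  # 80 shared
  # union 100: concordance exactly 0.8 -> same type
  k80 <- list(A = c(shared, keyset(seq(18001, 18901, by = 100))),
              B = c(shared, keyset(seq(19001, 19901, by = 100))))
  out <- assign_block_types(blocks, k80)
  expect_equal(out$type_label[1], out$type_label[2])
  # 79 shared of union 100 -> 0.79 < 0.8 -> different types
  shared79 <- shared[-1]
  k79 <- list(A = c(shared79, keyset(seq(18001, 19001, by = 100))),
              B = c(shared79, keyset(seq(19101, 20101, by = 100))))
  out <- assign_block_types(blocks, k79)
  expect_false(out$type_label[1] == out$type_label[2])
})

test_that("identity approximation can veto a concordant pair", {
  blocks <- mk_blocks(c("A", "B"), start = 1000, end = 2000)  # 1001 bp
  shared <- keyset(seq(1010, 1980, by = 120))  # 9 shared
  ka <- c(shared, keyset(1501))    # 1 private each: concordance 9/11 = 0.82
  kb <- c(shared, keyset(1601))
  keys <- list(A = ka, B = kb)
  # 2 discordant positions over 1001 bp: identity 0.998002 >= 0.998 -> linked
  out <- assign_block_types(blocks, keys, typing_params())
  expect_equal(out$type_label[1], out$type_label[2])
  # stricter identity threshold unlinks the same pair
  out <- assign_block_types(blocks, keys, typing_params(min_identity = 0.999))
  expect_false(out$type_label[1] == out$type_label[2])
  # concordance-only mode ignores identity
  out <- assign_block_types(blocks, keys,
                            typing_params(min_identity = 0.999,
                                          use_identity = FALSE))
  expect_equal(out$type_label[1], out$type_label[2])
})

test_that("types close transitively with a non-metric warning", {
  blocks <- mk_blocks(c("A", "B", "C"))
  base <- seq(2000, 20000, by = 200)  # 91 positions
  kb <- keyset(base)
  ka <- keyset(c(base[-(1:10)], seq(2100, 3900, by = 200)))
  kc <- keyset(c(base[-(82:91)], seq(10100, 11900, by = 200)))
  keys <- list(A = ka, B = kb, C = kc)
  expect_gte(snv_concordance(ka, kb), 0.8)
  expect_gte(snv_concordance(kb, kc), 0.8)
  expect_lt(snv_concordance(ka, kc), 0.8)
  expect_warning(
    out <- assign_block_types(blocks, keys,
                              typing_params(use_identity = FALSE)),
    "transitivity")
  expect_equal(length(unique(out$type_label)), 1)
})

test_that("disjoint loci get distinct consecutive labels in genomic order", {
  blocks <- rbind(mk_blocks(c("A", "B"), 1000, 21000),
                  mk_blocks(c("A", "B"), 50000, 70000))
  keys <- list(A = c(keyset(seq(1100, 20900, by = 200)),
                     keyset(seq(50100, 69900, by = 200))),
               B = c(keyset(seq(1100, 20900, by = 200)),
                     keyset(seq(50100, 69900, by = 200))))
  out <- assign_block_types(blocks, keys)
  expect_equal(sort(unique(out$type_label)), c(1L, 2L))
  expect_equal(out$type_label[out$start == 1000], c(1L, 1L))
  expect_equal(out$type_label[out$start == 50000], c(2L, 2L))
})

test_that("carried variant keys reflect per-sample genotypes", {
  vt <- read_vcf(fixture_vcf())
  k1 <- carried_variant_keys(vt, "S1")
  expect_true("chr1:10000:A" %in% k1)       # 0/1 carries the alt
  expect_false("chr1:55000:A" %in% k1)      # 0/0 does not
  expect_false(any(grepl(":54000:", carried_variant_keys(vt, "S2"))))  # ./.
})
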