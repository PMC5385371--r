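small_cfg <- function(seed = 101, ...) {
  cross_sim_config(n_founders = 4, n_chromosomes = 1, chrom_len = 1e6,
                   n_dvb_per_chrom = 6, seed = seed, ...)
}

test_that("the simulator is deterministic for a fixed seed", {
  a <- simulate_founders(small_cfg())
  b <- simulate_founders(small_cfg())
  expect_identical(a, b)
  c <- simulate_founders(small_cfg(seed = 202))
  expect_false(identical(a$variants, c$variants))
})

test_that("zero sparse density leaves sparse regions variant-free", {
  fp <- simulate_founders(small_cfg(sparse_density = 0))
  v <- fp$variants
  lay <- fp$layout
  in_dense <- vapply(seq_len(nrow(v)), function(i) {
    any(lay$chrom == v$chrom[i] & lay$start <= v$pos[i] & lay$end >= v$pos[i])
  }, logical(1))
  expect_true(all(in_dense))
})

test_that("planted dense blocks are recovered where founders carry variants", {
  cfg <- cross_sim_config(n_founders = 2, n_chromosomes = 1,
                          n_dvb_per_chrom = 10, n_haplotypes = 2,
                          sparse_density = 0, seed = 5)
  fp <- simulate_founders(cfg)
  vt <- cultivar_variant_table(fp)
  p <- segmentation_params()
  for (f in fp$founders) {
    blocks <- segment_panel(vt, fp$chrom_lengths, p, samples = f)
    dv <- blocks[blocks$klass == "dvb", ]
    carried <- fp$layout$dvb[fp$hap_assign[f, ] > 1]
    planted <- fp$layout[fp$layout$dvb %in% carried, ]
    # every carried planted block recovered within one window
    expect_equal(nrow(dv), nrow(planted))
    expect_true(all(abs(dv$start - planted$start) <= p$window_bp))
    expect_true(all(abs(dv$end - planted$end) <= p$window_bp))
  }
})

test_that("F1 offspring are heterozygous wherever inbred parents differ", {
  set.seed(77)
  fp <- simulate_founders(small_cfg())
  f1 <- simulate_cross(fp$genomes$F01, fp$genomes$F02, fp, type = "F1")
  vt <- cultivar_variant_table(fp)
  blocks <- segment_panel(vt, fp$chrom_lengths)
  cand <- extract_candidate_indels(vt, blocks)
  gt <- genotype_panel(fp, list(F01 = fp$genomes$F01, F02 = fp$genomes$F02,
                                F1 = f1), cand, mutation_rate = 0)
  differs <- gt$calls["F01", ] != gt$calls["F02", ]
  expect_true(all(grepl("/", gt$calls["F1", differs])))
  expect_true(all(gt$calls["F1", !differs] == gt$calls["F01", !differs]))
})

test_that("selfing erodes heterozygosity and doubling removes it", {
  set.seed(78)
  fp <- simulate_founders(small_cfg())
  vt <- cultivar_variant_table(fp)
  blocks <- segment_panel(vt, fp$chrom_lengths)
  cand <- extract_candidate_indels(vt, blocks)
  het_frac <- function(g) {
    gt <- genotype_panel(fp, list(X = g), cand, mutation_rate = 0)
    mean(grepl("/", gt$calls["X", ]))
  }
  f1 <- simulate_cross(fp$genomes$F01, fp$genomes$F02, fp, type = "F1")
  f5 <- simulate_cross(fp$genomes$F01, fp$genomes$F02, fp, type = "self",
                       n_generations = 4)
  dh <- simulate_cross(fp$genomes$F01, fp$genomes$F02, fp, type = "F1",
                       inbred = TRUE)
  expect_gt(het_frac(f1), het_frac(f5))
  expect_equal(het_frac(dh), 0)
})

test_that("simulated trios are pedigree-consistent at zero mutation rate", {
  set.seed(79)
  fp <- simulate_founders(small_cfg())
  off <- simulate_cross(fp$genomes$F03, fp$genomes$F04, fp, type = "F1")
  vt <- cultivar_variant_table(fp)
  blocks <- segment_panel(vt, fp$chrom_lengths)
  cand <- extract_candidate_indels(vt, blocks)
  gt <- genotype_panel(fp, list(F03 = fp$genomes$F03, F04 = fp$genomes$F04,
                                O = off), cand, mutation_rate = 0)
  bm <- suppressWarnings(encode_genotypes(gt, "F03"))
  r <- pedigree_consistency(bm, "O", "F03", "F04")
  expect_equal(r$rate, 0)
})

test_that("mutation noise perturbs genotypes at roughly the configured rate", {
  set.seed(80)
  fp <- simulate_founders(small_cfg())
  vt <- cultivar_variant_table(fp)
  blocks <- segment_panel(vt, fp$chrom_lengths)
  cand <- extract_candidate_indels(vt, blocks)
  g0 <- genotype_panel(fp, fp$genomes, cand, mutation_rate = 0)
  g1 <- genotype_panel(fp, fp$genomes, cand, mutation_rate = 0.2)
  changed <- mean(g0$calls != g1$calls)
  expect_gt(changed, 0.05)
  expect_lt(changed, 0.4)
})

test_that("loci outside the simulated chromosomes are rejected", {
  fp <- simulate_founders(small_cfg())
  bad <- data.frame(id = "x", chrom = "chr1", pos = 2e6, ref_len = 13L,
                    alt_lens = "1", indel_size = 12L, dvb = "1")
  expect_error(genotype_panel(fp, fp$genomes, bad), "outside")
})

test_that("crossover placement is depleted inside dense blocks", {
  set.seed(81)
  fp <- simulate_founders(small_cfg())
  est <- estimate_recomb_ratio(fp, n_meioses = 3000)
  expect_gt(est$ratio, 3)   # configured 6.6, loose check at this n
  expect_lt(est$ratio, 12)
})
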