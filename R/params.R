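#' Segmentation parameters
#'
#' Controls the sliding-window classification of a chromosome into dense and
#' sparse variation blocks. A window is dense when its variant density
#' (variants per kb, SNVs and InDels together) reaches `density_threshold`;
#' dense windows are unioned, runs separated by at most `merge_gap_bp` are
#' merged, and dense blocks shorter than `min_block_bp` are reclassified
#' sparse. All comparisons are inclusive (`>=`).
#'
#' Defaults (10 kb windows, 2 kb step, 1.5 variants/kb, 10 kb merge gap and
#' minimum block size) produce dense blocks on the sub-100 kb scale typical
#' of gene-rich regions when applied to resequencing-density variant calls.
#'
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts in bp; must not exceed
#'   `window_bp`.
#' @param density_threshold Variants per kb at or above which a window is
#'   dense.
#' @param min_block_bp Minimum width of an emitted dense block.
#' @param merge_gap_bp Maximum gap between dense runs merged into one block.
#' @return An object of class `segmentation_params`.
#' @export
#' @examples
#' segmentation_params(window_bp = 5000, density_threshold = 2)
segmentation_params <- function(window_bp = 10000L, step_bp = 2000L,
                                density_threshold = 1.5,
                                min_block_bp = 10000L,
                                merge_gap_bp = 10000L) {
  window_bp <- as.integer(window_bp)
  step_bp <- as.integer(step_bp)
  min_block_bp <- as.integer(min_block_bp)
  merge_gap_bp <- as.integer(merge_gap_bp)
  stopifnot(step_bp >= 1L, window_bp >= step_bp,
            density_threshold > 0, min_block_bp >= 1L, merge_gap_bp >= 0L)
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 density_threshold = density_threshold,
                 min_block_bp = min_block_bp, merge_gap_bp = merge_gap_bp),
            class = "segmentation_params")
}

#' Block-typing parameters
#'
#' Two dense blocks at the same locus in different cultivars are "the same
#' type" (descend from a common parental haplotype) when their sequence
#' identity is at least `min_identity` (default 99.8\%) and their SNV
#' concordance is at least `min_concordance` (default 0.8). Blocks are only
#' compared when their reciprocal overlap reaches `min_reciprocal_overlap`.
#' Thresholds are inclusive.
#'
#' @param min_identity Minimum approximate sequence identity, in (0, 1].
#' @param min_concordance Minimum SNV concordance (Jaccard), in (0, 1].
#' @param min_reciprocal_overlap Minimum reciprocal overlap fraction for two
#'   blocks to be considered the same locus.
#' @param use_identity If `FALSE`, typing uses concordance alone (identity
#'   cannot always be derived from variant calls).
#' @return An object of class `typing_params`.
#' @export
typing_params <- function(min_identity = 0.998, min_concordance = 0.8,
                          min_reciprocal_overlap = 0.5,
                          use_identity = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_concordance > 0, min_concordance <= 1,
            min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1)
  structure(list(min_identity = min_identity,
                 min_concordance = min_concordance,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 use_identity = isTRUE(use_identity)),
            class = "typing_params")
}

#' Cross-simulation configuration
#'
#' Defines a synthetic panel: founder genomes laid out as alternating sparse
#' and dense variation blocks, per-block variant densities, and a meiosis
#' model in which the per-bp crossover intensity in sparse blocks is
#' `recomb_ratio` times that in dense blocks (default 6.6), so dense blocks
#' are inherited largely intact.
#'
#' Founders carry one of a small number of ancestral haplotypes per dense
#' block (haplotype 0 is the reference, i.e. variant-free); distinct
#' haplotypes share individual variants with probability `share_prob`, which
#' creates non-trivial block typing. InDel sizes are drawn uniformly on
#' `indel_size_range` so downstream length filters see both passes and
#' failures.
#'
#' @param n_founders Number of founder genomes.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_len Chromosome length in bp (recycled across chromosomes).
#' @param n_dvb_per_chrom Planted dense blocks per chromosome.
#' @param dvb_len_range Dense-block length range in bp.
#' @param dense_density Variants per kb inside dense blocks.
#' @param sparse_density Variants per kb in sparse regions.
#' @param n_haplotypes Ancestral haplotypes per dense block (including the
#'   reference haplotype).
#' @param share_prob Probability that a variant of one ancestral haplotype is
#'   shared by another haplotype of the same block.
#' @param indel_frac Fraction of dense-block variants that are InDels (the
#'   rest are SNVs).
#' @param indel_size_range InDel size range in bp.
#' @param recomb_ratio Sparse:dense per-bp crossover-rate ratio; must
#'   exceed 1.
#' @param crossovers_mean Mean crossovers per chromosome per meiosis
#'   (Poisson).
#' @param mutation_rate Per-marker, per-genotyping probability of a spurious
#'   pattern change.
#' @param seed Integer seed fixing all simulator output.
#' @return An object of class `cross_sim_config`.
#' @export
cross_sim_config <- function(n_founders = 6L, n_chromosomes = 2L,
                             chrom_len = 1e6, n_dvb_per_chrom = 8L,
                             dvb_len_range = c(30000, 60000),
                             dense_density = 5, sparse_density = 0.1,
                             n_haplotypes = 3L, share_prob = 0.3,
                             indel_frac = 0.3,
                             indel_size_range = c(1L, 30L),
                             recomb_ratio = 6.6, crossovers_mean = 2,
                             mutation_rate = 0, seed = 1L) {
  stopifnot(n_founders >= 2L, n_chromosomes >= 1L, chrom_len > 0,
            n_dvb_per_chrom >= 1L, recomb_ratio > 1,
            dense_density > sparse_density, sparse_density >= 0,
            n_haplotypes >= 2L, share_prob >= 0, share_prob <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_len = as.numeric(chrom_len),
                 n_dvb_per_chrom = as.integer(n_dvb_per_chrom),
                 dvb_len_range = as.numeric(dvb_len_range),
                 dense_density = dense_density,
                 sparse_density = sparse_density,
                 n_haplotypes = as.integer(n_haplotypes),
                 share_prob = share_prob,
                 indel_frac = indel_frac,
                 indel_size_range = as.integer(indel_size_range),
                 recomb_ratio = recomb_ratio,
                 crossovers_mean = crossovers_mean,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "cross_sim_config")
}
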