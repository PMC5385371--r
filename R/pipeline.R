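#' Run the full barcode pipeline on a variant table
#'
#' Chains the whole workflow: per-cultivar segmentation into variation
#' blocks, cross-cultivar dense-block typing, InDel candidate extraction
#' and filtering, per-dVB marker selection, genotyping, barcode encoding
#' against the reference cultivar, simple-matching distances, a
#' neighbor-joining tree and the minimal discriminating marker set.
#'
#' @param variants A `variant_table` (from [read_vcf()] or
#'   [cultivar_variant_table()]). The reference cultivar need not be a
#'   column: it is all-reference by construction and is added as such.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param reference Reference cultivar id.
#' @param seg_params,typ_params Segmentation and typing parameters.
#' @param min_indel,max_indel InDel size bounds in bp.
#' @param per_dvb_quota Markers per dense-block type.
#' @param policy Het/missing policy for distance computations.
#' @return A list of class `vb_pipeline`: `blocks` (typed), `candidates`,
#'   `markers` (selected), `genotypes`, `barcodes`, `dist`, `tree`,
#'   `minset`.
#' @export
run_pipeline <- function(variants, chrom_lengths, reference = "REF",
                         seg_params = segmentation_params(),
                         typ_params = typing_params(),
                         min_indel = 5L, max_indel = 20L,
                         per_dvb_quota = 1L, policy = "exclude") {
  samples <- attr(variants, "samples")
  if (!reference %in% samples) {
    variants[[reference]] <- "0/0"
    variants <- variant_table(variants, samples = c(samples, reference))
    samples <- c(samples, reference)
  }
  blocks <- segment_panel(variants, chrom_lengths, seg_params,
                          samples = setdiff(samples, reference))
  keys <- lapply(setNames(nm = setdiff(samples, reference)),
                 function(cv) carried_variant_keys(variants, cv))
  blocks <- assign_block_types(blocks, keys, typ_params)
  cand <- extract_candidate_indels(variants, blocks, min_indel, max_indel)
  gt_all <- candidate_genotypes(variants, cand)
  markers <- select_markers(cand, gt_all, per_dvb_quota = per_dvb_quota)
  sel <- match(markers$id, gt_all$markers$id)
  gt <- genotype_table(gt_all$markers[sel, , drop = FALSE], gt_all$cultivars,
                       gt_all$calls[, sel, drop = FALSE])
  bm <- encode_genotypes(gt, reference)
  bd <- barcode_dist(bm, policy)
  tree <- if (nrow(bm) >= 2) nj_tree(bd$distance) else NULL
  ms <- minimal_discriminating_set(bm)
  structure(list(blocks = blocks, candidates = cand, markers = markers,
                 genotypes = gt, barcodes = bm, dist = bd, tree = tree,
                 minset = ms),
            class = "vb_pipeline")
}

#' @export
print.vb_pipeline <- function(x, ...) {
  nd <- sum(x$blocks$klass == "dvb")
  cat("vb_pipeline:", nd, "dense blocks (",
      length(unique(x$blocks$type_label[x$blocks$klass == "dvb"])),
      "types),", nrow(x$candidates), "InDel candidates,",
      nrow(x$markers), "selected markers,",
      nrow(x$barcodes), "cultivars\n")
  cat("  minimal discriminating set:", length(x$minset$markers),
      "markers;", nrow(x$minset$unresolved), "unresolved pairs\n")
  invisible(x)
}
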