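#' Read variant records from a VCF file
#'
#' Thin reader over [vcfR::read.vcfR()] that returns one row per VCF record
#' in (chrom, pos) order, with multi-allelic records kept intact (not split),
#' so third-allele patterns survive downstream. Genotypes are returned as one
#' column per sample holding GT strings (`"0/1"`, `"1|1"`, ...; `NA` for
#' missing).
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param samples Optional character vector of sample names to keep; all
#'   samples by default. Requesting an absent sample is an error.
#' @return A `variant_table`: a data.frame with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (comma-separated alternate alleles), then one
#'   genotype column per sample.
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  present <- colnames(vcf@gt)[-1]
  if (is.null(samples)) samples <- present
  missing <- setdiff(samples, present)
  if (length(missing) > 0) {
    stop("unknown sample: ", paste(missing, collapse = ", "))
  }
  # enforce sorted input rather than silently reordering
  ord_ok <- all(tapply(pos, chrom, function(p) !is.unsorted(p)))
  if (!isTRUE(ord_ok)) stop("unsorted VCF: positions decrease within a chromosome")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = length(pos), dimnames = dimnames(gt))
  tab <- data.frame(chrom = chrom, pos = pos,
                    ref = as.character(fix[, "REF"]),
                    alt = as.character(fix[, "ALT"]),
                    stringsAsFactors = FALSE)
  for (s in samples) tab[[s]] <- unname(gt[, s])
  variant_table(tab, samples = samples)
}

#' Construct a variant table
#'
#' @param df data.frame with columns `chrom`, `pos`, `ref`, `alt` and one
#'   genotype column per sample.
#' @param samples Character vector naming the genotype columns.
#' @return The data.frame with class `variant_table` and a `samples`
#'   attribute.
#' @export
variant_table <- function(df, samples = character()) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)),
            all(samples %in% names(df)))
  if (any(df$pos < 1)) stop("variant positions must be >= 1")
  if (any(!nzchar(df$ref))) stop("ref allele must be non-empty")
  structure(df, class = c("variant_table", "data.frame"), samples = samples)
}

#' Allele lengths and InDel size of variant records
#'
#' A record is an InDel when some alternate allele length differs from the
#' reference length; `indel_size` is the largest absolute length difference
#' across alternate alleles (0 for SNVs).
#'
#' @param variants A `variant_table` (or data.frame with `ref`, `alt`).
#' @return Integer vector of InDel sizes, one per record.
#' @export
indel_size <- function(variants) {
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  reflen <- nchar(variants$ref)
  vapply(seq_along(alts), function(i) {
    max(abs(nchar(alts[[i]]) - reflen[i]))
  }, integer(1))
}

#' @rdname indel_size
#' @export
is_indel <- function(variants) indel_size(variants) > 0L

# allele index (0 = ref) per haplotype from a GT string; NA for missing
parse_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
  parts <- strsplit(gt, "[/|]")[[1]]
  idx <- suppressWarnings(as.integer(parts))
  if (length(idx) == 1) idx <- c(idx, idx)
  idx[1:2]
}
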