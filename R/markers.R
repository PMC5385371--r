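#' Extract dVB-specific InDel candidates
#'
#' Keeps the variant records that (i) are InDels with size between `min_size`
#' and `max_size` bp inclusive (size = largest absolute length difference
#' between an alternate allele and the reference allele; SNVs are excluded)
#' and (ii) lie inside a dense variation block. The 5–20 bp default window
#' targets InDels resolvable as distinct bands on an agarose gel.
#'
#' @param variants A `variant_table`.
#' @param blocks A `variation_blocks` data.frame; containment is tested
#'   against its dense (`klass == "dvb"`) rows.
#' @param min_size,max_size InDel size bounds in bp (inclusive).
#' @return A data.frame of class `indel_candidates` with columns `id`,
#'   `chrom`, `pos`, `ref_len`, `alt_lens` (comma-separated), `indel_size`,
#'   `dvb` (host block's type label, or `chrom:start-end` when untyped).
#' @export
extract_candidate_indels <- function(variants, blocks, min_size = 5L,
                                     max_size = 20L) {
  dv <- blocks[blocks$klass == "dvb", , drop = FALSE]
  sz <- indel_size(variants)
  keep <- which(sz >= min_size & sz <= max_size)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    hit <- which(dv$chrom == variants$chrom[i] &
                   dv$start <= variants$pos[i] & dv$end >= variants$pos[i])
    if (length(hit) == 0) next
    h <- hit[1]
    dvb_id <- if (!is.na(dv$type_label[h])) {
      as.character(dv$type_label[h])
    } else paste0(dv$chrom[h], ":", dv$start[h], "-", dv$end[h])
    alt_l <- nchar(strsplit(variants$alt[i], ",", fixed = TRUE)[[1]])
    rows[[k]] <- data.frame(
      id = paste0(variants$chrom[i], "_", variants$pos[i]),
      chrom = variants$chrom[i], pos = variants$pos[i],
      ref_len = nchar(variants$ref[i]),
      alt_lens = paste(alt_l, collapse = ","),
      indel_size = sz[i], dvb = dvb_id, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), chrom = character(0), pos = integer(0),
               ref_len = integer(0), alt_lens = character(0),
               indel_size = integer(0), dvb = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("indel_candidates", "data.frame")
  out
}

#' Amplicon-size filter for a marker candidate
#'
#' Given flank widths (bp of primer-to-InDel sequence on each side), the
#' expected PCR product for an allele of length L is
#' `flank_left + L + flank_right`. A candidate is kept only when every
#' allele's product falls inside `[min_len, max_len]` (default 80–120 bp),
#' so all alleles yield scorable bands.
#'
#' @param allele_lens Integer vector of allele lengths in bp (reference
#'   first, by convention).
#' @param flank_left,flank_right Flank widths in bp (each >= 1).
#' @param min_len,max_len Admissible amplicon size range (inclusive).
#' @return A list with `keep` (logical) and `sizes` (per-allele amplicon
#'   lengths).
#' @export
#' @examples
#' amplicon_filter(c(13, 1), 40, 40)  # sizes 93 and 81 -> keep
amplicon_filter <- function(allele_lens, flank_left, flank_right,
                            min_len = 80L, max_len = 120L) {
  stopifnot(flank_left >= 1, flank_right >= 1)
  sizes <- flank_left + allele_lens + flank_right
  list(keep = all(sizes >= min_len & sizes <= max_len), sizes = sizes)
}

#' Default flank widths centring the reference amplicon on a target size
#'
#' Splits `target - ref_len` bp of flanking sequence as evenly as possible
#' between the two sides, so the reference allele's amplicon is `target` bp.
#'
#' @param ref_len Reference allele length in bp.
#' @param target Target reference amplicon size (default 100 bp).
#' @return `c(flank_left, flank_right)`.
#' @export
default_flanks <- function(ref_len, target = 100L) {
  tot <- max(2L, target - ref_len)
  c(tot %/% 2L, tot - tot %/% 2L)
}

#' Polymorphism information content
#'
#' PIC of a marker is one minus the sum of squared pattern frequencies:
#' `PIC = 1 - sum_j p_j^2`, where `p_j` is the frequency of the j-th band
#' pattern among scored (non-missing) cultivars. It is 0 for a monomorphic
#' marker and at most `1 - 1/n` for n patterns (0.5 for a biallelic marker).
#'
#' @param counts Non-negative pattern counts; at least one must be positive.
#'   Missing calls must already be excluded.
#' @return The PIC value (not rounded; reports conventionally round to two
#'   decimals).
#' @export
#' @examples
#' round(pic(c(76, 71)), 2)  # 0.50
#' round(pic(c(4, 143)), 2)  # 0.05
pic <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative pattern count")
  tot <- sum(counts)
  if (tot == 0) stop("all pattern counts are zero")
  1 - sum((counts / tot)^2)
}

#' Pattern frequencies and PIC for one marker's calls
#'
#' Each distinct call string (including heterozygous `"x/y"` composites) is
#' one band pattern; missing calls (`"."`) are dropped, not imputed.
#'
#' @param calls Character vector of per-cultivar calls.
#' @return List with `counts` (named), `n_scored`, `missing_frac`,
#'   `n_patterns`, `pic`.
#' @export
marker_stats <- function(calls) {
  n <- length(calls)
  scored <- calls[calls != "." & !is.na(calls)]
  counts <- table(scored)
  list(counts = counts, n_scored = length(scored),
       missing_frac = 1 - length(scored) / n,
       n_patterns = length(counts),
       pic = if (length(scored)) pic(as.numeric(counts)) else NA_real_)
}

#' Genotype a candidate panel from a variant table
#'
#' Converts per-sample VCF genotypes at candidate loci into band patterns:
#' each allele's pattern is its expected amplicon size in bp (alleles of
#' equal length are indistinguishable on a gel and share a pattern), a
#' heterozygous call with two distinct sizes becomes `"s1/s2"` (smaller
#' first), and missing genotypes propagate as `"."`.
#'
#' @param variants A `variant_table`.
#' @param candidates An `indel_candidates` data.frame.
#' @param target_amplicon Reference amplicon size used to derive flanks (see
#'   [default_flanks()]).
#' @return A [genotype_table()] whose markers carry `ref_pattern` (the
#'   reference allele's amplicon size).
#' @export
candidate_genotypes <- function(variants, candidates, target_amplicon = 100L) {
  samples <- attr(variants, "samples")
  key <- paste(variants$chrom, variants$pos)
  rows <- match(paste(candidates$chrom, candidates$pos), key)
  gts <- vapply(samples, function(s) variants[[s]][rows],
                character(length(rows)))
  gts <- matrix(gts, nrow = length(rows), dimnames = list(NULL, samples))
  i1 <- suppressWarnings(
    matrix(as.integer(sub("[/|].*", "", gts)), nrow = nrow(gts)))
  i2 <- suppressWarnings(
    matrix(as.integer(sub(".*[/|]", "", gts)), nrow = nrow(gts)))
  calls <- matrix(".", nrow = length(samples), ncol = nrow(candidates))
  ref_pattern <- character(nrow(candidates))
  for (j in seq_len(nrow(candidates))) {
    fl <- default_flanks(candidates$ref_len[j], target_amplicon)
    lens <- c(candidates$ref_len[j],
              as.integer(strsplit(candidates$alt_lens[j], ",")[[1]]))
    sizes <- fl[1] + lens + fl[2]
    ref_pattern[j] <- as.character(sizes[1])
    for (s in seq_along(samples)) {
      a <- i1[j, s]; b <- i2[j, s]
      if (is.na(a) || is.na(b)) next
      pat <- sort(unique(sizes[c(a, b) + 1]))
      calls[s, j] <- paste(pat, collapse = "/")
    }
  }
  markers <- data.frame(id = candidates$id, chrom = candidates$chrom,
                        pos = candidates$pos, dvb = candidates$dvb,
                        ref_pattern = ref_pattern, stringsAsFactors = FALSE)
  genotype_table(markers, samples, calls)
}

#' Select a marker panel from scored candidates
#'
#' Eligible candidates must pass the amplicon filter for every allele and
#' show at most `max_missing` missing calls (the panel-computable proxy for
#' genotyping success). Within each dense-block type, candidates are ranked
#' by PIC (descending), then allele-size difference (descending, larger gaps
#' resolve better on a gel), then position (ascending), and the top
#' `per_dvb_quota` are selected. Deterministic for fixed input.
#'
#' @param candidates An `indel_candidates` data.frame.
#' @param gt The candidates' [genotype_table()] (from
#'   [candidate_genotypes()]).
#' @param per_dvb_quota Markers to keep per dense-block type.
#' @param size_window Admissible amplicon range `c(min, max)`.
#' @param max_missing Maximum tolerated missing-call fraction.
#' @param target_amplicon Reference amplicon size for flank derivation.
#' @return A data.frame of selected markers (`id`, `chrom`, `pos`, `dvb`,
#'   `sizes`, `size_diff`, `pic`), ordered by (chrom, pos), with attribute
#'   `uncovered_dvbs` listing dense-block types with no eligible candidate.
#' @export
select_markers <- function(candidates, gt, per_dvb_quota = 1L,
                           size_window = c(80L, 120L), max_missing = 0.1,
                           target_amplicon = 100L) {
  n <- nrow(candidates)
  stat <- lapply(seq_len(n), function(j) marker_stats(gt$calls[, j]))
  keep <- logical(n); sizes <- character(n); sdiff <- numeric(n)
  for (j in seq_len(n)) {
    fl <- default_flanks(candidates$ref_len[j], target_amplicon)
    lens <- c(candidates$ref_len[j],
              as.integer(strsplit(candidates$alt_lens[j], ",")[[1]]))
    amp <- amplicon_filter(lens, fl[1], fl[2], size_window[1], size_window[2])
    sizes[j] <- paste(amp$sizes, collapse = ",")
    sdiff[j] <- max(amp$sizes) - min(amp$sizes)
    keep[j] <- amp$keep && stat[[j]]$missing_frac <= max_missing
  }
  picv <- vapply(stat, function(s) ifelse(is.na(s$pic), 0, s$pic), numeric(1))
  sel <- integer(0)
  for (d in unique(candidates$dvb)) {
    ix <- which(keep & candidates$dvb == d)
    if (length(ix) == 0) next
    ix <- ix[order(-picv[ix], -sdiff[ix], candidates$pos[ix])]
    sel <- c(sel, head(ix, per_dvb_quota))
  }
  out <- data.frame(id = candidates$id[sel], chrom = candidates$chrom[sel],
                    pos = candidates$pos[sel], dvb = candidates$dvb[sel],
                    sizes = sizes[sel], size_diff = sdiff[sel],
                    pic = picv[sel], stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  covered <- unique(candidates$dvb[keep])
  attr(out, "uncovered_dvbs") <- setdiff(unique(candidates$dvb), covered)
  out
}
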