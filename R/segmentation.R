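#' Segment a chromosome into dense and sparse variation blocks
#'
#' Classifies sliding windows as dense when their variant density (variants
#' per kb) reaches the threshold, unions dense windows into runs, merges runs
#' separated by at most `merge_gap_bp`, and reclassifies dense runs shorter
#' than `min_block_bp` as sparse. The returned blocks tile `[1, chrom_len]`
#' with alternating classes. All thresholds are inclusive.
#'
#' @param positions Sorted 1-based variant positions for one cultivar and
#'   chromosome (SNVs and InDels together).
#' @param chrom_len Chromosome length in bp.
#' @param params A [segmentation_params()] object.
#' @param chrom Chromosome id recorded in the output.
#' @param cultivar Cultivar id recorded in the output.
#' @return A data.frame of class `variation_blocks` with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `klass` (`"dvb"`/`"svb"`),
#'   `cultivar`, `density` (variants/kb), `type_label` (`NA`, filled in by
#'   [assign_block_types()]).
#' @export
#' @examples
#' p <- segmentation_params(window_bp = 10000, density_threshold = 1)
#' segment_variation_blocks(seq(400001, 450000, by = 100), 1e6, p)
segment_variation_blocks <- function(positions, chrom_len,
                                     params = segmentation_params(),
                                     chrom = "chr1", cultivar = NA_character_) {
  chrom_len <- as.numeric(chrom_len)
  positions <- as.numeric(positions)
  if (length(positions) && (min(positions) < 1 || max(positions) > chrom_len)) {
    stop("variant position outside [1, chrom_len]")
  }
  positions <- sort(positions)
  starts <- seq(1, chrom_len, by = params$step_bp)
  ends <- pmin(starts + params$window_bp - 1, chrom_len)
  counts <- findInterval(ends, positions) - findInterval(starts - 1, positions)
  dens <- counts / ((ends - starts + 1) / 1000)
  dense <- dens >= params$density_threshold
  runs <- merge_intervals(starts[dense], ends[dense], gap = 0)
  runs <- merge_intervals(runs$start, runs$end, gap = params$merge_gap_bp)
  keep <- (runs$end - runs$start + 1) >= params$min_block_bp
  runs <- runs[keep, , drop = FALSE]
  blocks <- tile_from_dense(runs, chrom_len)
  n_in <- findInterval(blocks$end, positions) -
    findInterval(blocks$start - 1, positions)
  out <- data.frame(chrom = chrom, start = blocks$start, end = blocks$end,
                    klass = blocks$klass, cultivar = cultivar,
                    density = n_in / ((blocks$end - blocks$start + 1) / 1000),
                    type_label = NA_integer_, stringsAsFactors = FALSE)
  class(out) <- c("variation_blocks", "data.frame")
  out
}

# union possibly-overlapping intervals, merging across gaps <= gap
merge_intervals <- function(start, end, gap = 0) {
  if (length(start) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] - me - 1 <= gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# complement dense runs into a full tiling of [1, chrom_len]
tile_from_dense <- function(runs, chrom_len) {
  if (nrow(runs) == 0) {
    return(data.frame(start = 1, end = chrom_len, klass = "svb"))
  }
  s <- c(); e <- c(); k <- c()
  cur <- 1
  for (i in seq_len(nrow(runs))) {
    if (runs$start[i] > cur) {
      s <- c(s, cur); e <- c(e, runs$start[i] - 1); k <- c(k, "svb")
    }
    s <- c(s, runs$start[i]); e <- c(e, runs$end[i]); k <- c(k, "dvb")
    cur <- runs$end[i] + 1
  }
  if (cur <= chrom_len) {
    s <- c(s, cur); e <- c(e, chrom_len); k <- c(k, "svb")
  }
  data.frame(start = s, end = e, klass = k)
}

#' Segment all cultivars and chromosomes of a variant table
#'
#' @param variants A `variant_table` (see [read_vcf()]).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param params A [segmentation_params()] object.
#' @param samples Cultivars to segment (default: all samples carried by the
#'   table). A cultivar's variant set is the records where it carries at
#'   least one non-reference allele.
#' @return A `variation_blocks` data.frame covering every cultivar and
#'   chromosome.
#' @export
segment_panel <- function(variants, chrom_lengths,
                          params = segmentation_params(), samples = NULL) {
  if (is.null(samples)) samples <- attr(variants, "samples")
  out <- list()
  for (cv in samples) {
    gts <- variants[[cv]]
    carried <- !is.na(gts) & grepl("[1-9]", gts)
    for (ch in names(chrom_lengths)) {
      sel <- carried & variants$chrom == ch
      out[[paste(cv, ch)]] <- segment_variation_blocks(
        variants$pos[sel], chrom_lengths[[ch]], params,
        chrom = ch, cultivar = cv)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("variation_blocks", "data.frame")
  res
}
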