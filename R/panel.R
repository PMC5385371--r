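#' Rank database cultivars by closeness to a query barcode
#'
#' Orders the panel by ascending marker-difference count to the query (ties
#' broken lexicographically by cultivar id) and reports the panel's mean
#' pairwise difference for context, so "3 markers apart" can be read against
#' the background divergence of unrelated cultivars.
#'
#' @param query A cultivar id present in `bm`, or a code vector (e.g. from
#'   [parse_barcode()]; its checksum, when present, must match the panel).
#' @param bm A `barcode_matrix` database.
#' @param k Number of matches to return (truncated to the database size).
#' @param policy Passed to [pairwise_difference()].
#' @return A data.frame (`cultivar`, `count`, `comparable_n`, `distance`)
#'   with attribute `mean_pairwise` (mean difference count over all
#'   database pairs).
#' @export
closest_matches <- function(query, bm, k = 5L, policy = "exclude") {
  if (is.character(query) && length(query) == 1 && query %in% rownames(bm)) {
    qrow <- bm[query, ]
    attr(qrow, "checksum") <- attr(bm, "checksum")
    db_ids <- setdiff(rownames(bm), query)
  } else {
    qrow <- query
    qc <- attr(qrow, "checksum")
    if (!is.null(qc) && !is.null(attr(bm, "checksum")) &&
        qc != attr(bm, "checksum")) stop("panel mismatch")
    db_ids <- rownames(bm)
  }
  res <- lapply(db_ids, function(cv) {
    pd <- pairwise_difference(unclass(qrow), bm[cv, ], policy)
    data.frame(cultivar = cv, count = pd$count,
               comparable_n = pd$comparable_n, distance = pd$distance,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(res$count, res$cultivar), , drop = FALSE]
  res <- head(res, min(k, nrow(res)))
  rownames(res) <- NULL
  bd <- barcode_dist(bm, policy)
  attr(res, "mean_pairwise") <- mean(bd$counts[upper.tri(bd$counts)])
  res
}

#' Check a trio's marker genotypes for pedigree consistency
#'
#' A marker is consistent when the offspring's code appears in at least one
#' parent, or the offspring is heterozygous while the parents carry
#' different codes (the Mendelian F1 case). Markers with a missing call in
#' any of the three cultivars are not comparable. Inconsistencies flag
#' either a pedigree error or a de novo change in the block.
#'
#' @param bm A `barcode_matrix`.
#' @param offspring,parent1,parent2 Cultivar ids.
#' @return List with `verdicts` (data.frame: marker, offspring/parent codes,
#'   comparable, consistent), `n_comparable`, `n_inconsistent` and `rate`
#'   (inconsistent / comparable).
#' @export
pedigree_consistency <- function(bm, offspring, parent1, parent2) {
  o <- bm[offspring, ]; p1 <- bm[parent1, ]; p2 <- bm[parent2, ]
  comp <- o != "." & p1 != "." & p2 != "."
  consistent <- (o == p1) | (o == p2) | (o == "h" & p1 != p2)
  consistent[!comp] <- NA
  verdicts <- data.frame(marker = colnames(bm), offspring = o,
                         parent1 = p1, parent2 = p2, comparable = comp,
                         consistent = consistent, stringsAsFactors = FALSE)
  rownames(verdicts) <- NULL
  n_comp <- sum(comp)
  n_bad <- sum(!consistent[comp])
  list(verdicts = verdicts, n_comparable = n_comp, n_inconsistent = n_bad,
       rate = if (n_comp > 0) n_bad / n_comp else NA_real_)
}

#' Heterozygosity (fixation) report
#'
#' Lists, per cultivar, the heterozygous markers grouped by the dense block
#' they tag. A cultivar with any heterozygous block is flagged "not fixed":
#' its genome still segregates there and further selfing is needed before
#' the line is uniform and stable.
#'
#' @param bm A `barcode_matrix` whose marker table carries `chrom` and
#'   `dvb`.
#' @return A data.frame (`cultivar`, `n_het_markers`, `n_blocks`, `fixed`)
#'   with attribute `blocks`: a data.frame of (cultivar, chrom, dvb,
#'   n_markers) runs.
#' @export
fixation_report <- function(bm) {
  m <- attr(bm, "markers")
  rows <- list(); blocks <- list()
  for (cv in rownames(bm)) {
    het <- which(bm[cv, ] == "h")
    if (length(het)) {
      grp <- unique(data.frame(cultivar = cv, chrom = m$chrom[het],
                               dvb = m$dvb[het], stringsAsFactors = FALSE))
      grp$n_markers <- vapply(seq_len(nrow(grp)), function(i) {
        sum(m$chrom[het] == grp$chrom[i] & m$dvb[het] == grp$dvb[i])
      }, integer(1))
      blocks[[cv]] <- grp
    }
    rows[[cv]] <- data.frame(cultivar = cv, n_het_markers = length(het),
                             n_blocks = if (length(het)) nrow(blocks[[cv]]) else 0L,
                             fixed = length(het) == 0L,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "blocks") <- if (length(blocks)) {
    b <- do.call(rbind, blocks); rownames(b) <- NULL; b
  } else {
    data.frame(cultivar = character(0), chrom = character(0),
               dvb = character(0), n_markers = integer(0))
  }
  out
}
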