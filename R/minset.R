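#' Minimal discriminating marker set
#'
#' Finds a small marker subset that still tells every pair of cultivars
#' apart, as a set cover: the universe is the unordered cultivar pairs, and
#' each marker covers the pairs at which the two cultivars carry different
#' homozygous codes (`a`/`b`/`c`; heterozygous and missing calls do not
#' discriminate). The default greedy cover repeatedly picks the marker
#' covering the most uncovered pairs, breaking ties by higher PIC and then
#' genomic order, and stops when all coverable pairs are covered or no
#' marker adds coverage. Pairs with identical usable codes everywhere are
#' unresolvable and reported as such.
#'
#' A redundancy-elimination pass follows the greedy cover: any selected
#' marker whose removal still leaves every covered pair distinguished is
#' dropped (checked in reverse selection order), so early greedy picks made
#' redundant by later ones do not inflate the subset.
#'
#' `exact = TRUE` switches to exhaustive search over subsets of increasing
#' size (guaranteed minimum; only sensible for panels of ~20 markers or
#' fewer).
#'
#' @param bm A `barcode_matrix`.
#' @param pairs Optional two-column matrix of cultivar-id pairs that must be
#'   resolved; all pairs by default.
#' @param pic_values Optional named numeric vector of marker PICs used for
#'   tie-breaking; computed from the code frequencies when absent.
#' @param exact Use exhaustive search instead of the greedy cover.
#' @return A list of class `marker_subset`: `markers` (selected ids),
#'   `resolved_pairs`, `n_pairs`, `unresolved` (data.frame of cultivar
#'   pairs no marker distinguishes).
#' @export
minimal_discriminating_set <- function(bm, pairs = NULL, pic_values = NULL,
                                       exact = FALSE) {
  ids <- rownames(bm)
  if (length(ids) < 2) {
    return(structure(list(markers = character(0), resolved_pairs = 0L,
                          n_pairs = 0L,
                          unresolved = data.frame(a = character(0),
                                                  b = character(0))),
                     class = "marker_subset"))
  }
  if (is.null(pairs)) pairs <- t(combn(ids, 2))
  np <- nrow(pairs)
  hom <- c("a", "b", "c")
  ia <- match(pairs[, 1], ids); ib <- match(pairs[, 2], ids)
  # cover[m, p]: marker m distinguishes pair p
  cover <- matrix(FALSE, ncol(bm), np)
  for (m in seq_len(ncol(bm))) {
    va <- bm[ia, m]; vb <- bm[ib, m]
    cover[m, ] <- va %in% hom & vb %in% hom & va != vb
  }
  coverable <- colSums(cover) > 0
  unresolved <- data.frame(a = pairs[!coverable, 1], b = pairs[!coverable, 2],
                           stringsAsFactors = FALSE)
  if (is.null(pic_values)) {
    pic_values <- apply(bm, 2, function(col) {
      cnt <- table(col[col %in% hom])
      if (length(cnt)) pic(as.numeric(cnt)) else 0
    })
  }
  picv <- pic_values[colnames(bm)]
  picv[is.na(picv)] <- 0
  target <- which(coverable)
  if (exact) {
    sel <- exact_cover(cover[, target, drop = FALSE])
  } else {
    sel <- integer(0)
    uncovered <- target
    while (length(uncovered) > 0) {
      gain <- rowSums(cover[, uncovered, drop = FALSE])
      gain[sel] <- -1
      best <- which(gain == max(gain))
      if (max(gain) <= 0) break
      best <- best[order(-picv[best], best)][1]  # PIC, then genomic order
      sel <- c(sel, best)
      uncovered <- uncovered[!cover[best, uncovered]]
    }
    covered <- target[colSums(cover[sel, target, drop = FALSE]) > 0]
    for (m in rev(sel)) {  # drop picks made redundant by later ones
      rest <- setdiff(sel, m)
      if (length(rest) &&
          all(colSums(cover[rest, covered, drop = FALSE]) > 0)) {
        sel <- rest
      }
    }
  }
  structure(list(markers = colnames(bm)[sel],
                 resolved_pairs = sum(coverable),
                 n_pairs = np, unresolved = unresolved),
            class = "marker_subset")
}

# smallest subset of rows covering all columns, by exhaustive search
exact_cover <- function(cover) {
  m <- nrow(cover)
  if (ncol(cover) == 0) return(integer(0))
  for (k in seq_len(m)) {
    combos <- combn(m, k)
    for (ci in seq_len(ncol(combos))) {
      rows <- combos[, ci]
      if (all(colSums(cover[rows, , drop = FALSE]) > 0)) return(rows)
    }
  }
  seq_len(m)
}

#' @export
print.marker_subset <- function(x, ...) {
  cat("marker_subset:", length(x$markers), "markers resolving",
      x$resolved_pairs, "of", x$n_pairs, "pairs\n")
  if (nrow(x$unresolved)) {
    cat("  unresolved pairs:", nrow(x$unresolved), "\n")
  }
  invisible(x)
}
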