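#' Pairwise barcode differences
#'
#' Counts the markers at which two barcode rows differ and derives the
#' simple-matching distance (differences / comparable markers). Under the
#' default `"exclude"` policy only markers where both calls are homozygous
#' codes (`a`, `b`, `c`) are comparable: heterozygous calls are a fixation
#' signal, not an identity signal, and missing calls carry no information.
#' `"mismatch"` treats `h` as a code of its own; `"match-either"` lets `h`
#' match any non-missing code.
#'
#' @param rowA,rowB Character vectors of codes (rows of a `barcode_matrix`,
#'   or outputs of [parse_barcode()]). When both carry a `checksum`
#'   attribute the checksums must agree.
#' @param policy Heterozygous/missing handling policy.
#' @return List with `count` (integer differences), `comparable_n`, and
#'   `distance` (`count / comparable_n`).
#' @export
pairwise_difference <- function(rowA, rowB,
                                policy = c("exclude", "mismatch",
                                           "match-either")) {
  policy <- match.arg(policy)
  ca <- attr(rowA, "checksum"); cb <- attr(rowB, "checksum")
  if (!is.null(ca) && !is.null(cb) && ca != cb) stop("panel mismatch")
  if (length(rowA) != length(rowB)) stop("rows differ in length")
  hom <- c("a", "b", "c")
  if (policy == "exclude") {
    comp <- rowA %in% hom & rowB %in% hom
    diff <- comp & rowA != rowB
  } else if (policy == "mismatch") {
    comp <- rowA != "." & rowB != "."
    diff <- comp & rowA != rowB
  } else {
    comp <- rowA != "." & rowB != "."
    diff <- comp & rowA != rowB & rowA != "h" & rowB != "h"
  }
  n <- sum(comp)
  if (n == 0) stop("no comparable markers: distance undefined")
  list(count = sum(diff), comparable_n = n, distance = sum(diff) / n)
}

#' Simple-matching distance matrix for a barcode panel
#'
#' @param bm A `barcode_matrix`.
#' @param policy Passed to [pairwise_difference()].
#' @return A list of class `barcode_dist` with `counts` (integer difference
#'   counts), `comparable` (comparable marker counts) and `distance`
#'   (simple-matching distance matrix, zero diagonal, symmetric).
#' @export
barcode_dist <- function(bm, policy = "exclude") {
  n <- nrow(bm)
  ids <- rownames(bm)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  comp <- matrix(ncol(bm), n, n, dimnames = list(ids, ids))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      pd <- pairwise_difference(bm[i, ], bm[j, ], policy)
      counts[i, j] <- counts[j, i] <- pd$count
      comp[i, j] <- comp[j, i] <- pd$comparable_n
      D[i, j] <- D[j, i] <- pd$distance
    }
  }
  structure(list(counts = counts, comparable = comp, distance = D),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("barcode_dist over", nrow(x$distance), "cultivars; mean difference",
      round(mean(x$counts[upper.tri(x$counts)]), 1), "markers\n")
  invisible(x)
}
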