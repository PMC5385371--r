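#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou–Nei neighbor joining with two determinism guarantees:
#' ties on the Q criterion are broken by the lexicographically smallest pair
#' of node labels (an internal node inherits the smallest tip label beneath
#' it), and negative branch lengths are clamped to zero with the deficit
#' moved onto the sister branch so the path length through the new node is
#' preserved. On an additive distance matrix the generating tree's topology
#' and branch lengths are recovered exactly.
#'
#' @param d Symmetric numeric matrix with dimnames (e.g. the `distance`
#'   element of [barcode_dist()]), or a `dist` object. All entries must be
#'   finite.
#' @return An unrooted `phylo` object ([ape]).
#' @export
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' nj_tree(d)  # branches A:0.05 B:0.15 C:0.25
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa")
  if (any(!is.finite(d))) stop("non-finite distance")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- labs          # newick fragment per active node
  lead <- labs          # lexicographic leader label per active node
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        frag[1], d[1, 2] / 2,
                                        frag[2], d[1, 2] / 2))
    return(tr)
  }
  while (n > 3) {
    r <- rowSums(d)
    best <- NULL; bestq <- Inf
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      pick <- FALSE
      if (q < bestq - 1e-12) {
        pick <- TRUE
      } else if (abs(q - bestq) <= 1e-12) {
        pr <- sort(c(lead[i], lead[j])); pb <- sort(c(lead[best[1]], lead[best[2]]))
        if (pr[1] < pb[1] || (pr[1] == pb[1] && pr[2] < pb[2])) pick <- TRUE
      }
      if (pick) { best <- c(i, j); bestq <- q }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    newlead <- min(lead[i], lead[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    lead <- c(lead[keep], newlead)
    n <- n - 1
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ln <- c(l1, l2, l3)
  if (any(ln < 0)) {
    deficit <- sum(pmin(ln, 0))
    ln <- pmax(ln, 0)
    pos <- ln > 0
    ln[pos] <- ln[pos] + deficit / sum(pos)  # spread over remaining branches
  }
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], ln[1], frag[2], ln[2], frag[3], ln[3])
  ape::read.tree(text = txt)
}

#' Cut a tree into groups at a height threshold
#'
#' Utility for reading major groups off a clustering tree: the tree is
#' rooted at its midpoint-free default root and tips are grouped by the
#' connected components obtained after removing internal edges longer than
#' `threshold`.
#'
#' @param tree A `phylo` object.
#' @param threshold Edge-length threshold; internal edges longer than this
#'   are cut.
#' @return Named integer vector: group id per tip label.
#' @export
cut_tree_groups <- function(tree, threshold) {
  keep <- tree$edge.length <= threshold |
    tree$edge[, 2] <= length(tree$tip.label)  # never cut terminal edges
  n_node <- max(tree$edge)
  parent <- seq_len(n_node)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in which(keep)) {
    a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(length(tree$tip.label)), find, integer(1))
  setNames(match(roots, unique(roots)), tree$tip.label)
}
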