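#' SNV concordance between two blocks' variant sets
#'
#' The concordance of two dense blocks at the same locus in two cultivars is
#' the Jaccard index of their (position, alternate-allele) sets: shared
#' variants over the union. Two empty sets are fully concordant (1.0).
#'
#' @param a,b Character vectors of variant keys (e.g. `"1042:A"`), or
#'   data.frames with columns `pos` and `allele`.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' snv_concordance(c("10:A", "20:T"), c("10:A", "30:G"))  # 1/3
snv_concordance <- function(a, b) {
  a <- variant_keys(a); b <- variant_keys(b)
  u <- union(a, b)
  if (length(u) == 0) return(1.0)
  length(intersect(a, b)) / length(u)
}

variant_keys <- function(x) {
  if (is.data.frame(x)) paste(x$pos, x$allele, sep = ":") else as.character(x)
}

#' Per-cultivar carried-variant keys from a variant table
#'
#' For each record where the cultivar carries a non-reference allele, emits
#' one key `"chrom:pos:allele"` per distinct carried alternate allele.
#'
#' @param variants A `variant_table`.
#' @param cultivar Sample name.
#' @return Character vector of keys.
#' @export
carried_variant_keys <- function(variants, cultivar) {
  gts <- variants[[cultivar]]
  cand <- which(!is.na(gts) & grepl("[1-9]", gts))
  if (length(cand) == 0) return(character(0))
  alts <- strsplit(variants$alt[cand], ",", fixed = TRUE)
  keys <- vector("list", length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    idx <- parse_gt(gts[i])
    idx <- unique(idx[!is.na(idx) & idx > 0])
    keys[[k]] <- paste(variants$chrom[i], variants$pos[i],
                       alts[[k]][idx], sep = ":")
  }
  unlist(keys)
}

#' Assign shared type labels to dense blocks across cultivars
#'
#' Two dense blocks from different cultivars are candidates for the same type
#' when their reciprocal overlap reaches `min_reciprocal_overlap`. A
#' candidate pair is linked when, restricted to the pair's intersection
#' interval, SNV concordance is at least `min_concordance` and (when
#' `use_identity`) the approximate sequence identity — one minus the density
#' of discordant variant positions over the intersection length — is at
#' least `min_identity` (identity cannot be computed exactly from variant
#' calls alone; the approximation treats every discordant position as one
#' mismatching base). Type labels are the connected components of this graph
#' (transitive closure), numbered consecutively in genomic order of each
#' component's leftmost block. Components containing an overlapping pair
#' that itself fails the thresholds are reported with a warning (non-metric
#' cluster, joined by transitivity only).
#'
#' @param blocks A `variation_blocks` data.frame (all cultivars); only
#'   `klass == "dvb"` rows receive labels.
#' @param cultivar_keys Named list, per cultivar, of carried-variant key
#'   vectors as produced by [carried_variant_keys()].
#' @param params A [typing_params()] object.
#' @return `blocks` with `type_label` filled for dense blocks.
#' @export
assign_block_types <- function(blocks, cultivar_keys,
                               params = typing_params()) {
  dv <- which(blocks$klass == "dvb")
  n <- length(dv)
  if (n == 0) return(blocks)
  b <- blocks[dv, , drop = FALSE]
  # per-block (pos, key) sets, restricted once to the block's own span
  key_pos <- lapply(cultivar_keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)
    list(chrom = vapply(parts, `[`, "", 1),
         pos = as.numeric(vapply(parts, `[`, "", 2)),
         key = paste(vapply(parts, `[`, "", 2),
                     vapply(parts, `[`, "", 3), sep = ":"))
  })
  bk <- vector("list", n)
  for (i in seq_len(n)) {
    kp <- key_pos[[b$cultivar[i]]]
    if (is.null(kp)) {
      bk[[i]] <- list(pos = numeric(0), key = character(0))
    } else {
      sel <- kp$chrom == b$chrom[i] & kp$pos >= b$start[i] & kp$pos <= b$end[i]
      bk[[i]] <- list(pos = kp$pos[sel], key = kp$key[sel])
    }
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  failed_pairs <- list()
  linked_pairs <- list()
  for (ch in unique(b$chrom)) {
    ix <- which(b$chrom == ch)
    ix <- ix[order(b$start[ix])]
    for (a_i in seq_along(ix)) {
      i <- ix[a_i]
      for (a_j in seq_along(ix)[-seq_len(a_i)]) {
        j <- ix[a_j]
        if (b$start[j] > b$end[i]) break  # sorted by start: no more overlap
        ov_s <- max(b$start[i], b$start[j]); ov_e <- min(b$end[i], b$end[j])
        ov <- ov_e - ov_s + 1
        li <- b$end[i] - b$start[i] + 1; lj <- b$end[j] - b$start[j] + 1
        if (ov / li < params$min_reciprocal_overlap ||
            ov / lj < params$min_reciprocal_overlap) next
        ki <- bk[[i]]$key[bk[[i]]$pos >= ov_s & bk[[i]]$pos <= ov_e]
        kj <- bk[[j]]$key[bk[[j]]$pos >= ov_s & bk[[j]]$pos <= ov_e]
        conc <- snv_concordance(ki, kj)
        ok <- conc >= params$min_concordance
        if (ok && params$use_identity) {
          disc <- length(unique(c(setdiff(ki, kj), setdiff(kj, ki))))
          ok <- (1 - disc / ov) >= params$min_identity
        }
        if (ok) {
          linked_pairs[[length(linked_pairs) + 1]] <- c(i, j)
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        } else {
          failed_pairs[[length(failed_pairs) + 1]] <- c(i, j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  for (p in failed_pairs) {
    if (comp[p[1]] == comp[p[2]]) {
      warning("non-metric type cluster: blocks joined by transitivity only")
      break
    }
  }
  comp_min <- tapply(seq_len(n), comp, function(ii) {
    ii[order(b$chrom[ii], b$start[ii])][1]
  })
  ord <- order(b$chrom[comp_min], b$start[comp_min])
  relabel <- setNames(seq_along(ord), names(comp_min)[ord])
  blocks$type_label[dv] <- unname(relabel[as.character(comp)])
  blocks
}
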