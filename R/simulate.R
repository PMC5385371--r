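#' Simulate founder genomes with a planted variation-block layout
#'
#' Lays out alternating sparse and dense blocks on each chromosome, draws a
#' pool of variants per dense block, groups them into a small number of
#' ancestral haplotypes (haplotype 1 is the reference, variant-free;
#' distinct non-reference haplotypes share individual pool variants with the
#' configured probability), and assigns every founder one haplotype per
#' dense block. Sparse regions receive low-density founder-private
#' variants. InDel sizes span the configured range so downstream length
#' filters see both passes and failures. All output is fixed by
#' `config$seed`.
#'
#' @param config A [cross_sim_config()].
#' @return A `founder_panel` object: `config`, `chrom_lengths` (named),
#'   `layout` (planted dense blocks: chrom, dvb, start, end), `variants`
#'   (pool: chrom, pos, ref, alt, ref_len, alt_len, is_indel, dvb),
#'   `carriage` (founders x variants logical), `hap_assign` (founders x
#'   planted blocks), `genomes` (named list of founder mosaic genomes),
#'   `founders` (ids).
#' @export
simulate_founders <- function(config = cross_sim_config()) {
  set.seed(config$seed)
  nf <- config$n_founders
  founders <- sprintf("F%02d", seq_len(nf))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(config$chrom_len,
                                length.out = config$n_chromosomes), chroms)
  min_gap <- 40000
  layout <- list(); var_list <- list(); carr_list <- list()
  hap_assign <- NULL
  for (ch in chroms) {
    L <- chrom_lengths[[ch]]
    nd <- config$n_dvb_per_chrom
    lens <- round(runif(nd, config$dvb_len_range[1], config$dvb_len_range[2]))
    free <- L - sum(lens) - (nd + 1) * min_gap
    if (free < 0) stop("chromosome too short for the requested block layout")
    extra <- diff(c(0, sort(runif(nd, 0, free)), free))
    gaps <- min_gap + round(extra)
    starts <- cumsum(gaps[seq_len(nd)] + c(0, lens[-nd])) + 1
    # keep within chromosome
    ends <- starts + lens - 1
    lay <- data.frame(chrom = ch, dvb = paste0(ch, "_d", seq_len(nd)),
                      start = starts, end = pmin(ends, L),
                      stringsAsFactors = FALSE)
    layout[[ch]] <- lay
    ha <- matrix(sample.int(config$n_haplotypes, nf * nd, replace = TRUE),
                 nrow = nf, dimnames = list(founders, lay$dvb))
    hap_assign <- cbind(hap_assign, ha)
    for (d in seq_len(nd)) {
      len_kb <- (lay$end[d] - lay$start[d] + 1) / 1000
      q <- 2 * config$share_prob / (1 + config$share_prob)
      if (q <= 0) q <- 1
      n_pool <- max(1L, round(config$dense_density * len_kb / q))
      pos <- sort(sample(seq(lay$start[d], lay$end[d]), n_pool))
      v <- make_variants(ch, pos, config, dvb = lay$dvb[d])
      # haplotype h >= 2 carries each pool variant with prob q (independent),
      # giving expected pairwise Jaccard q/(2-q) = share_prob between
      # distinct non-reference haplotypes and per-haplotype density ~ dense
      hap_carries <- matrix(FALSE, config$n_haplotypes, n_pool)
      for (h in seq(2, config$n_haplotypes)) {
        hap_carries[h, ] <- runif(n_pool) < q
      }
      carr <- hap_carries[ha[, d], , drop = FALSE]
      rownames(carr) <- founders
      var_list[[paste(ch, d)]] <- v
      carr_list[[paste(ch, d)]] <- carr
    }
    # sparse-region private variants
    if (config$sparse_density > 0) {
      sv_iv <- sparse_intervals(lay, L)
      sv_bp <- sum(sv_iv$end - sv_iv$start + 1)
      n_sv <- round(config$sparse_density * sv_bp / 1000) * nf
      if (n_sv > 0) {
        pool <- unlist(mapply(seq, sv_iv$start, sv_iv$end, SIMPLIFY = FALSE))
        pos <- sort(sample(pool, min(n_sv, length(pool))))
        v <- make_variants(ch, pos, config, dvb = NA_character_)
        carr <- matrix(FALSE, nf, length(pos), dimnames = list(founders, NULL))
        owner <- sample.int(nf, length(pos), replace = TRUE)
        carr[cbind(owner, seq_along(pos))] <- TRUE
        var_list[[paste(ch, "sv")]] <- v
        carr_list[[paste(ch, "sv")]] <- carr
      }
    }
  }
  variants <- do.call(rbind, var_list)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  carriage <- do.call(cbind, carr_list)[, o, drop = FALSE]
  genomes <- lapply(seq_len(nf), function(f) {
    segs <- lapply(chroms, function(ch) {
      s <- data.frame(start = 1, end = chrom_lengths[[ch]], founder = f)
      list(h1 = s, h2 = s)
    })
    names(segs) <- chroms
    segs
  })
  names(genomes) <- founders
  structure(list(config = config, chrom_lengths = chrom_lengths,
                 layout = do.call(rbind, c(layout, make.row.names = FALSE)),
                 variants = variants, carriage = carriage,
                 hap_assign = hap_assign, genomes = genomes,
                 founders = founders),
            class = "founder_panel")
}

make_variants <- function(ch, pos, config, dvb) {
  n <- length(pos)
  is_ind <- runif(n) < config$indel_frac
  size <- sample(seq(config$indel_size_range[1], config$indel_size_range[2]),
                 n, replace = TRUE)
  del <- runif(n) < 0.5
  ref_len <- ifelse(is_ind, ifelse(del, size + 1L, 1L), 1L)
  alt_len <- ifelse(is_ind, ifelse(del, 1L, size + 1L), 1L)
  data.frame(chrom = ch, pos = pos,
             ref = strrep("A", ref_len), alt = strrep("C", alt_len),
             ref_len = ref_len, alt_len = alt_len, is_indel = is_ind,
             dvb = dvb, stringsAsFactors = FALSE)
}

sparse_intervals <- function(lay, L) {
  s <- c(1, lay$end + 1)
  e <- c(lay$start - 1, L)
  keep <- e >= s
  data.frame(start = s[keep], end = e[keep])
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$founders), "founders,",
      length(x$chrom_lengths), "chromosomes,",
      nrow(x$layout), "planted dense blocks,",
      nrow(x$variants), "pool variants\n")
  invisible(x)
}

# one gamete from a mosaic genome; crossover count ~ Poisson, positions by
# inverse CDF over piecewise-constant intensity (dense blocks weight 1,
# sparse regions weight recomb_ratio)
gamete <- function(genome, panel) {
  config <- panel$config
  out <- list()
  for (ch in names(genome)) {
    L <- panel$chrom_lengths[[ch]]
    lay <- panel$layout[panel$layout$chrom == ch, , drop = FALSE]
    n_co <- rpois(1, config$crossovers_mean)
    xo <- if (n_co > 0) sample_crossovers(n_co, lay, L, config$recomb_ratio)
          else numeric(0)
    first <- sample(c("h1", "h2"), 1)
    out[[ch]] <- recombine(genome[[ch]], sort(xo), first, L)
  }
  out
}

sample_crossovers <- function(n, lay, L, ratio) {
  # piecewise weights: sparse = ratio, dense = 1
  sv <- sparse_intervals(lay, L)
  segs <- rbind(data.frame(start = sv$start, end = sv$end, w = ratio),
                data.frame(start = lay$start, end = lay$end, w = 1))
  segs <- segs[order(segs$start), , drop = FALSE]
  mass <- (segs$end - segs$start + 1) * segs$w
  cum <- cumsum(mass)
  u <- runif(n, 0, cum[length(cum)])
  i <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  i[i > nrow(segs)] <- nrow(segs)
  segs$start[i] + (u - c(0, cum)[i]) / segs$w[i]
}

recombine <- function(chrom_haps, xo, first, L) {
  bounds <- c(1, floor(xo) + 1, L + 1)
  use <- rep(c(first, setdiff(c("h1", "h2"), first)),
             length.out = length(bounds) - 1)
  segs <- list()
  for (k in seq_len(length(bounds) - 1)) {
    s <- bounds[k]; e <- bounds[k + 1] - 1
    if (e < s) next
    h <- chrom_haps[[use[k]]]
    sel <- h$end >= s & h$start <= e
    sub <- h[sel, , drop = FALSE]
    sub$start[1] <- s
    sub$end[nrow(sub)] <- e
    segs[[k]] <- sub
  }
  out <- do.call(rbind, segs)
  # merge adjacent segments from the same founder
  same <- c(FALSE, out$founder[-1] == out$founder[-nrow(out)] &
              out$start[-1] == out$end[-nrow(out)] + 1)
  grp <- cumsum(!same)
  data.frame(start = tapply(out$start, grp, min),
             end = tapply(out$end, grp, max),
             founder = tapply(out$founder, grp, `[`, 1),
             row.names = NULL)
}

#' Simulate a cross between two genomes
#'
#' Meiosis places a Poisson number of crossovers per chromosome with per-bp
#' intensity proportional to 1 inside planted dense blocks and
#' `recomb_ratio` in sparse regions, so dense blocks are inherited largely
#' intact. `"F1"` joins one gamete from each parent; `"self"` selfs the F1
#' for `n_generations` rounds (halving expected heterozygosity each round);
#' `"backcross"` crosses the F1 (and its successors) back to `parentB` (the
#' recurrent parent) for `n_generations` rounds, leaving an expected
#' `(1/2)^(n_generations + 1)` of the donor genome. `inbred = TRUE` finishes
#' with a doubled gamete (a fully homozygous derivative, as in
#' backcross-inbred or doubled-haploid lines).
#'
#' @param parentA,parentB Mosaic genomes (elements of `panel$genomes`, or
#'   prior outputs of this function). For backcrosses, `parentA` is the
#'   donor and `parentB` the recurrent parent.
#' @param panel The `founder_panel` the genomes live on.
#' @param type `"F1"`, `"self"`, or `"backcross"`.
#' @param n_generations Selfing or backcross generations after the F1.
#' @param inbred Finish with a doubled gamete.
#' @return A mosaic genome: per chromosome, two haplotypes, each a
#'   data.frame of (start, end, founder-of-origin) segments tiling the
#'   chromosome.
#' @export
simulate_cross <- function(parentA, parentB, panel,
                           type = c("F1", "self", "backcross"),
                           n_generations = 0L, inbred = FALSE) {
  type <- match.arg(type)
  join <- function(gA, gB) {
    setNames(lapply(names(gA), function(ch) list(h1 = gA[[ch]], h2 = gB[[ch]])),
             names(gA))
  }
  cur <- join(gamete(parentA, panel), gamete(parentB, panel))
  if (type == "self") {
    for (i in seq_len(n_generations)) {
      cur <- join(gamete(cur, panel), gamete(cur, panel))
    }
  } else if (type == "backcross") {
    for (i in seq_len(n_generations)) {
      cur <- join(gamete(cur, panel), gamete(parentB, panel))
    }
  }
  if (inbred) {
    g <- gamete(cur, panel)
    cur <- join(g, g)
  }
  cur
}

# founder-of-origin for each (chrom, pos) on one haplotype
founder_at <- function(genome, chrom, pos, hap) {
  segs <- genome[[chrom]][[hap]]
  segs$founder[findInterval(pos, segs$start)]
}

#' Variant table for a set of simulated cultivars
#'
#' Projects each cultivar's mosaic genome onto the founder variant pool:
#' a haplotype carries a variant when its founder-of-origin at that position
#' does. Output is a [variant_table()] with `"0/1"`-style genotypes, the
#' same shape [read_vcf()] produces, so the whole downstream pipeline runs
#' unchanged on simulated data.
#'
#' @param panel A `founder_panel`.
#' @param genomes Named list of mosaic genomes (defaults to the founders).
#' @return A `variant_table` with one genotype column per cultivar.
#' @export
cultivar_variant_table <- function(panel, genomes = panel$genomes) {
  v <- panel$variants
  tab <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    stringsAsFactors = FALSE)
  for (cv in names(genomes)) {
    g <- genomes[[cv]]
    a1 <- integer(nrow(v)); a2 <- integer(nrow(v))
    for (ch in unique(v$chrom)) {
      ix <- which(v$chrom == ch)
      f1 <- founder_at(g, ch, v$pos[ix], "h1")
      f2 <- founder_at(g, ch, v$pos[ix], "h2")
      a1[ix] <- as.integer(panel$carriage[cbind(f1, ix)])
      a2[ix] <- as.integer(panel$carriage[cbind(f2, ix)])
    }
    tab[[cv]] <- paste(a1, a2, sep = "/")
  }
  variant_table(tab, samples = names(genomes))
}

#' Genotype a marker panel on simulated cultivars
#'
#' Bridges the simulator to the pipeline's genotype-table input: genotypes
#' the candidate loci on the given genomes (band pattern = expected amplicon
#' size of the carried allele, heterozygous mosaics give double patterns)
#' and then applies per-marker, per-cultivar mutation noise at
#' `mutation_rate` (a scored pattern is replaced by a different pattern of
#' the same marker).
#'
#' @param panel A `founder_panel`.
#' @param genomes Named list of mosaic genomes.
#' @param candidates An `indel_candidates` data.frame on the same
#'   coordinates.
#' @param mutation_rate Overrides `panel$config$mutation_rate` when given.
#' @return A [genotype_table()].
#' @export
genotype_panel <- function(panel, genomes, candidates,
                           mutation_rate = panel$config$mutation_rate) {
  bad <- candidates$pos > panel$chrom_lengths[candidates$chrom]
  if (any(is.na(bad) | bad)) stop("locus outside simulated chromosomes")
  vt <- cultivar_variant_table(panel, genomes)
  gt <- candidate_genotypes(vt, candidates)
  if (mutation_rate > 0) {
    for (j in seq_len(ncol(gt$calls))) {
      pats <- unique(gt$calls[gt$calls[, j] != ".", j])
      if (length(pats) < 2) next
      hit <- which(runif(nrow(gt$calls)) < mutation_rate &
                     gt$calls[, j] != ".")
      for (i in hit) {
        gt$calls[i, j] <- sample(setdiff(pats, gt$calls[i, j]), 1)
      }
    }
  }
  gt
}

#' Estimate the sparse:dense crossover-rate ratio from simulated meioses
#'
#' Draws `n_meioses` gametes from a founder genome, records every crossover
#' position, and estimates the per-bp crossover rate in sparse regions over
#' that in planted dense blocks — a check that the meiosis model honours the
#' configured recombination-rate ratio.
#'
#' @param panel A `founder_panel`.
#' @param n_meioses Number of meioses to simulate.
#' @return List with `ratio` (estimated sparse:dense per-bp rate ratio),
#'   `n_crossovers`, `dense_bp`, `sparse_bp`.
#' @export
estimate_recomb_ratio <- function(panel, n_meioses = 10000L) {
  config <- panel$config
  lay <- panel$layout
  dense_bp <- sum(lay$end - lay$start + 1)
  total_bp <- sum(panel$chrom_lengths)
  sparse_bp <- total_bp - dense_bp
  n_dense <- 0L; n_sparse <- 0L; n_tot <- 0L
  for (ch in names(panel$chrom_lengths)) {
    L <- panel$chrom_lengths[[ch]]
    lc <- lay[lay$chrom == ch, , drop = FALSE]
    n_co <- sum(rpois(n_meioses, config$crossovers_mean))
    if (n_co == 0) next
    xo <- sample_crossovers(n_co, lc, L, config$recomb_ratio)
    in_dense <- findInterval(xo, lc$start) >= 1 &
      xo <= lc$end[pmax(1, findInterval(xo, lc$start))]
    n_dense <- n_dense + sum(in_dense)
    n_sparse <- n_sparse + sum(!in_dense)
    n_tot <- n_tot + n_co
  }
  list(ratio = (n_sparse / sparse_bp) / (n_dense / dense_bp),
       n_crossovers = n_tot, dense_bp = dense_bp, sparse_bp = sparse_bp)
}

#' Donor-genome difference of a backcross line against its recurrent parent
#'
#' Convenience wrapper used in validation: breeds `n_reps` backcross-inbred
#' lines (BC`n_bc` then doubled gamete) from a donor x recurrent pair and
#' returns, per replicate, the fraction of parent-differing markers at which
#' the line differs from the recurrent parent. The expectation is
#' `(1/2)^(n_bc + 1)`.
#'
#' @param panel A `founder_panel`.
#' @param donor,recurrent Founder ids.
#' @param candidates Marker loci (`indel_candidates`).
#' @param n_bc Backcross generations after the F1.
#' @param n_reps Replicates.
#' @return Numeric vector of per-replicate difference fractions.
#' @export
backcross_difference <- function(panel, donor, recurrent, candidates,
                                 n_bc = 5L, n_reps = 200L) {
  gt_par <- genotype_panel(panel, panel$genomes[c(donor, recurrent)],
                           candidates, mutation_rate = 0)
  differing <- which(gt_par$calls[donor, ] != gt_par$calls[recurrent, ])
  vapply(seq_len(n_reps), function(r) {
    off <- simulate_cross(panel$genomes[[donor]], panel$genomes[[recurrent]],
                          panel, type = "backcross", n_generations = n_bc,
                          inbred = TRUE)
    gt <- genotype_panel(panel, list(BC = off), candidates, mutation_rate = 0)
    mean(gt$calls["BC", differing] != gt_par$calls[recurrent, differing])
  }, numeric(1))
}
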