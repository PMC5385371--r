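# shared fixture builders; everything is generated in code at test time

# minimal barcode_matrix from a character matrix of codes
bm_from_codes <- function(codes, chrom = NULL, dvb = NULL,
                          reference = rownames(codes)[1]) {
  ids <- colnames(codes)
  if (is.null(ids)) {
    ids <- sprintf("m%02d", seq_len(ncol(codes)))
    colnames(codes) <- ids
  }
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("cv%02d", seq_len(nrow(codes)))
  }
  markers <- data.frame(
    id = ids,
    chrom = if (is.null(chrom)) "chr1" else chrom,
    pos = seq_len(ncol(codes)) * 1000L,
    dvb = if (is.null(dvb)) as.character(seq_len(ncol(codes))) else dvb,
    stringsAsFactors = FALSE)
  structure(codes, class = "barcode_matrix", markers = markers,
            reference = reference, checksum = panel_checksum(ids))
}

# random barcode matrix over {a, b}
random_bm <- function(n_cv, n_mk) {
  codes <- matrix(sample(c("a", "b"), n_cv * n_mk, replace = TRUE),
                  n_cv, n_mk)
  bm_from_codes(codes)
}

# brute-force minimum discriminating subset size (independent oracle)
brute_min_cover_size <- function(bm) {
  ids <- rownames(bm)
  pairs <- t(combn(ids, 2))
  hom <- c("a", "b", "c")
  dist_m <- function(cols) {
    all(apply(pairs, 1, function(p) {
      va <- bm[p[1], cols]; vb <- bm[p[2], cols]
      any(va %in% hom & vb %in% hom & va != vb)
    }))
  }
  # restrict universe to resolvable pairs
  resolvable <- apply(pairs, 1, function(p) {
    va <- bm[p[1], ]; vb <- bm[p[2], ]
    any(va %in% hom & vb %in% hom & va != vb)
  })
  pairs <- pairs[resolvable, , drop = FALSE]
  if (nrow(pairs) == 0) return(0L)
  covers <- function(cols) {
    all(apply(pairs, 1, function(p) {
      va <- bm[p[1], cols]; vb <- bm[p[2], cols]
      any(va %in% hom & vb %in% hom & va != vb)
    }))
  }
  for (k in seq_len(ncol(bm))) {
    cmb <- combn(ncol(bm), k)
    for (i in seq_len(ncol(cmb))) {
      if (covers(cmb[, i])) return(k)
    }
  }
  ncol(bm)
}

# independent brute-force window segmentation oracle
oracle_segment <- function(positions, chrom_len, params) {
  starts <- seq(1, chrom_len, by = params$step_bp)
  dense_iv <- NULL
  for (s in starts) {
    e <- min(s + params$window_bp - 1, chrom_len)
    dens <- sum(positions >= s & positions <= e) / ((e - s + 1) / 1000)
    if (dens >= params$density_threshold) {
      dense_iv <- rbind(dense_iv, c(s, e))
    }
  }
  if (is.null(dense_iv)) {
    return(data.frame(start = 1, end = chrom_len, klass = "svb"))
  }
  # union, merge across gaps, drop short
  iv <- dense_iv[order(dense_iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  for (i in seq_len(nrow(iv))[-1]) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] - last[2] - 1 <= params$merge_gap_bp) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
    } else {
      merged[[length(merged) + 1]] <- iv[i, ]
    }
  }
  m <- do.call(rbind, merged)
  m <- m[(m[, 2] - m[, 1] + 1) >= params$min_block_bp, , drop = FALSE]
  out <- NULL
  cur <- 1
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] > cur) out <- rbind(out, c(cur, m[i, 1] - 1, 0))
    out <- rbind(out, c(m[i, 1], m[i, 2], 1))
    cur <- m[i, 2] + 1
  }
  if (cur <= chrom_len) out <- rbind(out, c(cur, chrom_len, 0))
  data.frame(start = out[, 1], end = out[, 2],
             klass = ifelse(out[, 3] == 1, "dvb", "svb"))
}

fixture_vcf <- function() {
  system.file("extdata", "indel_fixture.vcf", package = "vbcode")
}

# planted truth matching the fixture VCF
fixture_blocks <- function() {
  data.frame(chrom = "chr1", start = 50001, end = 60000, klass = "dvb",
             cultivar = "S1", density = 1, type_label = NA_integer_,
             stringsAsFactors = FALSE)
}
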