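# shared fixture builders for the test suite

# small solid-colour image block over a grey background; colours given as
# RGB triples, block is rows r1:r2, cols c1:c2
block_image <- function(h = 24, w = 24, blocks = list(), bg = c(128, 128, 128)) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  for (b in blocks) {
    for (ch in 1:3) img[b$rows, b$cols, ch] <- b$rgb[ch]
  }
  idcpheno::as_rgb_image(img)
}

# tiny genotype_matrix from an explicit dosage matrix
toy_geno <- function(dosages, chrom = NULL, pos = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  structure(list(
    dosages = dosages, chrom = chrom, pos = pos,
    snp_id = paste0("s", seq_len(m)),
    line_id = sprintf("L%03d", seq_len(nrow(dosages)))
  ), class = "genotype_matrix")
}

# well-separated labeled feature clusters in (Y%, B%) space, no rendering
feature_clusters <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  centres <- rbind(c(2, 0.2), c(15, 0.6), c(36, 2.5), c(62, 8), c(35, 30))
  sds <- rbind(c(0.8, 0.1), c(2, 0.2), c(2.2, 0.4), c(2.4, 1.2), c(3, 2.5))
  rows <- lapply(1:5, function(k) {
    data.frame(
      yellow_pct = pmax(0, rnorm(n_per_class, centres[k, 1], sds[k, 1])),
      brown_pct = pmax(0, rnorm(n_per_class, centres[k, 2], sds[k, 2])),
      label = k
    )
  })
  do.call(rbind, rows)
}
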