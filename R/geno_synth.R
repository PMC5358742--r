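#' Simulate inbred-line genotypes with local LD
#'
#' Generates homozygous biallelic dosages (0/2, no heterozygotes, emulating
#' fully inbred plant-introduction lines) at SNPs laid out on several
#' chromosomes. Local linkage disequilibrium follows a latent Gaussian AR(1)
#' process along each chromosome: each line's latent trait has adjacent-SNP
#' correlation \code{ld_rho} and is thresholded at the SNP's allele frequency,
#' so marginal frequencies are exact while the realized dosage correlation is
#' monotone in \code{ld_rho} (somewhat attenuated by dichotomisation).
#'
#' @param n_lines number of inbred lines.
#' @param m_snps total number of SNPs (split evenly across chromosomes).
#' @param n_chrom number of chromosomes.
#' @param ld_rho latent adjacent-SNP correlation in \code{[0, 1)}; 0.9 gives
#'   adjacent dosage r-squared around 0.5.
#' @param maf_range range the per-SNP minor allele frequencies are drawn
#'   from, a subset of \code{[0, 0.5]}.
#' @param missing_rate fraction of entries set missing (NA), in \code{[0, 1)}.
#' @param seed integer seed; same arguments + seed give an identical matrix.
#' @return A list of class \code{genotype_matrix}: \code{dosages}
#'   (\code{n_lines x m_snps}, values 0/2/NA), \code{chrom}, \code{pos}
#'   (strictly increasing within chromosome), \code{snp_id}, \code{line_id}.
#' @export
simulate_genotypes <- function(n_lines, m_snps, n_chrom = 4, ld_rho = 0.9,
                               maf_range = c(0.1, 0.5), missing_rate = 0,
                               seed = 1L) {
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (maf_range[1] < 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be within [0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  set.seed(seed)
  per_chr <- diff(round(seq(0, m_snps, length.out = n_chrom + 1)))
  p <- stats::runif(m_snps, maf_range[1], maf_range[2])
  thr <- stats::qnorm(p)
  dos <- matrix(0L, n_lines, m_snps)
  chrom <- integer(m_snps); pos <- integer(m_snps)
  j0 <- 0L
  for (ch in seq_len(n_chrom)) {
    m_ch <- per_chr[ch]
    if (m_ch == 0) next
    z <- stats::rnorm(n_lines)
    for (j in seq_len(m_ch)) {
      if (j > 1) z <- ld_rho * z + sqrt(1 - ld_rho^2) * stats::rnorm(n_lines)
      dos[, j0 + j] <- 2L * (z < thr[j0 + j])
    }
    chrom[j0 + seq_len(m_ch)] <- ch
    pos[j0 + seq_len(m_ch)] <- sort(sample.int(m_ch * 50000L, m_ch))
    j0 <- j0 + m_ch
  }
  if (missing_rate > 0) {
    miss <- stats::runif(length(dos)) < missing_rate
    dos[miss] <- NA
  }
  structure(list(
    dosages = dos, chrom = chrom, pos = pos,
    snp_id = sprintf("snp_%d_%d", chrom, pos),
    line_id = sprintf("line%04d", seq_len(n_lines))
  ), class = "genotype_matrix")
}

# subset a genotype_matrix by SNP column index
subset_snps <- function(g, keep) {
  structure(list(
    dosages = g$dosages[, keep, drop = FALSE],
    chrom = g$chrom[keep], pos = g$pos[keep],
    snp_id = g$snp_id[keep], line_id = g$line_id
  ), class = "genotype_matrix")
}

#' Trait architecture for phenotype simulation
#'
#' Describes the genetic architecture of the simulated IDC-like trait:
#' planted QTL (by SNP index, with either an explicit additive effect or a
#' target fraction of line-mean phenotypic variance), a marker-based
#' polygenic background, line-mean heritability, and the replication design.
#'
#' @param qtl data frame with column \code{snp} and either \code{effect}
#'   (additive effect per dosage unit) or \code{r2} (target fraction of
#'   line-mean phenotypic variance explained); may be \code{NULL}.
#' @param h2 line-mean heritability in \code{[0, 1]}.
#' @param n_reps replications per line (balanced design).
#' @param rep_var variance of the replication (block) effect.
#' @param residual_var per-observation residual variance used when
#'   \code{h2 = 0} (otherwise the residual variance is derived from
#'   \code{h2}).
#' @param spad_cor target correlation between the SPAD-like surrogate and the
#'   genetic value (negative by default: more chlorosis, less chlorophyll).
#' @param mean grand mean of the trait.
#' @return A list of class \code{trait_architecture}.
#' @export
trait_architecture <- function(qtl = NULL, h2 = 0.7, n_reps = 4,
                               rep_var = 0.05, residual_var = 1,
                               spad_cor = -0.6, mean = 3) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    if (!"snp" %in% names(qtl)) stop("qtl needs a `snp` column")
    if (is.null(qtl$effect)) qtl$effect <- NA_real_
    if (is.null(qtl$r2)) qtl$r2 <- NA_real_
    if (any(is.na(qtl$effect) & is.na(qtl$r2))) {
      stop("each QTL needs `effect` or `r2`")
    }
    if (h2 > 0 && sum(qtl$r2, na.rm = TRUE) > h2) {
      stop("total QTL r2 exceeds h2: heritability unreachable")
    }
  }
  structure(list(qtl = qtl, h2 = h2, n_reps = as.integer(n_reps),
                 rep_var = rep_var, residual_var = residual_var,
                 spad_cor = spad_cor, mean = mean),
            class = "trait_architecture")
}

#' Simulate replicated phenotypes and a SPAD-like surrogate
#'
#' Builds line genetic values as planted-QTL contributions plus a
#' marker-based polygenic term (small random effects on every non-QTL SNP,
#' hence kinship-correlated across lines), scales variances so the line-mean
#' heritability \code{sigma_g^2 / (sigma_g^2 + sigma_e^2 / n_reps)} hits the
#' architecture's \code{h2}, and emits one record per line x replication with
#' a common replication (block) effect and i.i.d. residuals. A QTL given as
#' \code{r2} receives the effect size that makes it explain that fraction of
#' line-mean phenotypic variance. The SPAD-like column is a line-level linear
#' function of the genetic value plus noise, tuned to the target correlation.
#'
#' @param g a [simulate_genotypes()] matrix (missing dosages are mean-imputed
#'   internally for the genetic value).
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @return A data frame of class \code{phenotype_table} with columns
#'   \code{line}, \code{rep}, \code{value}, \code{spad}; attribute
#'   \code{"genetic_values"} carries the true line genetic values.
#' @export
simulate_phenotypes <- function(g, arch = trait_architecture(), seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  set.seed(seed)
  dos <- g$dosages
  if (anyNA(dos)) {
    mu_j <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu_j[idx[, 2]]
  }
  n <- nrow(dos); m <- ncol(dos)
  qtl_idx <- integer(0)
  gv_qtl <- rep(0, n)
  v_qtl <- 0
  if (!is.null(arch$qtl) && nrow(arch$qtl) > 0) {
    if (any(arch$qtl$snp < 1 | arch$qtl$snp > m)) stop("QTL index out of range")
    qtl_idx <- arch$qtl$snp
    for (i in seq_len(nrow(arch$qtl))) {
      x <- dos[, arch$qtl$snp[i]]
      vx <- stats::var(x)
      if (vx == 0) stop("QTL SNP ", arch$qtl$snp[i], " is monomorphic")
      eff <- arch$qtl$effect[i]
      if (is.na(eff)) {
        if (arch$h2 <= 0) stop("QTL r2 requires h2 > 0")
        # V_qtl = r2 * VP = r2 * VG / h2, with VG normalised to 1
        eff <- sqrt((arch$qtl$r2[i] / arch$h2) / vx)
      }
      gv_qtl <- gv_qtl + eff * x
    }
    gv_qtl <- gv_qtl - mean(gv_qtl)
    v_qtl <- stats::var(gv_qtl)
  }

  if (arch$h2 > 0) {
    v_poly <- max(1 - v_qtl, 0)
    poly <- rep(0, n)
    if (v_poly > 1e-12) {
      bg <- setdiff(seq_len(m), qtl_idx)
      u <- stats::rnorm(length(bg), 0, 1)
      W <- scale(dos[, bg, drop = FALSE], center = TRUE, scale = FALSE)
      poly <- drop(W %*% u)
      if (stats::var(poly) > 0) poly <- poly * sqrt(v_poly / stats::var(poly))
    }
    gv <- gv_qtl + poly
    vg <- stats::var(gv)
    sigma_e2 <- arch$n_reps * vg * (1 - arch$h2) / arch$h2
  } else {
    gv <- rep(0, n)
    sigma_e2 <- arch$residual_var
  }

  rep_eff <- stats::rnorm(arch$n_reps, 0, sqrt(arch$rep_var))
  tab <- expand.grid(line = g$line_id, rep = seq_len(arch$n_reps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  li <- match(tab$line, g$line_id)
  tab$value <- arch$mean + gv[li] + rep_eff[tab$rep] +
    stats::rnorm(nrow(tab), 0, sqrt(sigma_e2))

  # SPAD-like surrogate at the configured correlation with the genetic value
  if (stats::sd(gv) > 0) {
    zg <- (gv - mean(gv)) / stats::sd(gv)
    noise <- stats::rnorm(n)
    noise <- stats::residuals(stats::lm(noise ~ zg))
    noise <- noise / stats::sd(noise)
    zs <- sign(arch$spad_cor) * abs(arch$spad_cor) * zg +
      sqrt(1 - arch$spad_cor^2) * noise
    spad <- 40 + 8 * zs
  } else {
    spad <- 40 + stats::rnorm(n, 0, 8)
  }
  tab$spad <- spad[li]
  attr(tab, "genetic_values") <- stats::setNames(arch$mean + gv, g$line_id)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write simulated genotypes to VCF and dosage CSV
#'
#' Emits a minimal VCF 4.2 with homozygous GT calls (0/0 for dosage 0, 1/1
#' for dosage 2, ./. for missing) and/or a plain dosage CSV with
#' chromosome/position header rows.
#'
#' @param g a \code{genotype_matrix}.
#' @param vcf,csv output paths (either may be \code{NULL} to skip).
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(g, vcf = NULL, csv = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(vcf)) {
    con <- file(vcf, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=idcpheno",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", g$line_id), collapse = "\t")), con)
    gt <- matrix("./.", nrow(g$dosages), ncol(g$dosages))
    gt[which(g$dosages == 0)] <- "0/0"
    gt[which(g$dosages == 2)] <- "1/1"
    lines <- vapply(seq_along(g$snp_id), function(j) {
      paste(c(g$chrom[j], g$pos[j], g$snp_id[j], "A", "T", ".", "PASS", ".",
              "GT", gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
    close(con)
  }
  if (!is.null(csv)) {
    df <- data.frame(snp = g$snp_id, chrom = g$chrom, pos = g$pos,
                     t(g$dosages), check.names = FALSE)
    colnames(df)[-(1:3)] <- g$line_id
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(c(vcf = vcf, csv = csv))
}

#' Read a dosage CSV written by [write_genotypes()]
#'
#' @param path CSV path with columns \code{snp}, \code{chrom}, \code{pos}
#'   and one column of 0/2 dosages per line.
#' @return A \code{genotype_matrix}.
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dos <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  structure(list(dosages = unname(dos), chrom = df$chrom, pos = df$pos,
                 snp_id = df$snp, line_id = colnames(df)[-(1:3)]),
            class = "genotype_matrix")
}
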