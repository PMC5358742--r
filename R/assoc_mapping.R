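#' SNP quality control: missing-rate filter, mode imputation, MAF filter
#'
#' Applies the genotype QC rules in their stated order: SNPs with a missing
#' rate above \code{max_missing} are removed first; remaining missing calls
#' are imputed to the per-SNP modal genotype (ties to the smaller dosage);
#' SNPs with minor allele frequency below \code{min_maf} after imputation are
#' then removed.
#'
#' @param g a \code{genotype_matrix}.
#' @param max_missing maximum tolerated per-SNP missing rate (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return A \code{genotype_matrix} with no missing entries.
#' @export
filter_snps <- function(g, max_missing = 0.10, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- colMeans(is.na(g$dosages))
  g <- subset_snps(g, miss <= max_missing)
  if (ncol(g$dosages) == 0) stop("all SNPs removed by the missing-rate filter")
  if (anyNA(g$dosages)) {
    for (j in which(colSums(is.na(g$dosages)) > 0)) {
      x <- g$dosages[, j]
      tab <- table(x)
      mode <- as.numeric(names(tab)[which.max(tab)])  # tie -> smaller dosage
      x[is.na(x)] <- mode
      g$dosages[, j] <- x
    }
  }
  p <- colMeans(g$dosages) / 2
  maf <- pmin(p, 1 - p)
  g <- subset_snps(g, maf >= min_maf)
  if (ncol(g$dosages) == 0) stop("all SNPs removed by the MAF filter")
  g
}

#' Line BLUPs from replicated phenotype records
#'
#' Aggregates plot-level records to one value per line with the random-effects
#' model \code{value = mu + line + rep + residual} fitted by REML (lme4),
#' returning \code{mu + BLUP(line)}. BLUPs shrink toward the grand mean; with
#' zero between-line variance every BLUP equals the mean (a valid degenerate
#' outcome, warned about). With a single replication the rep term is dropped.
#'
#' @param p a \code{phenotype_table} (columns \code{line}, \code{rep},
#'   \code{value}).
#' @return A list of class \code{line_blups}: \code{blups} (named numeric)
#'   and \code{varcomp} (line, rep and residual variances).
#' @export
compute_blups <- function(p) {
  stopifnot(all(c("line", "rep", "value") %in% names(p)))
  lines <- unique(p$line)
  if (length(lines) < 2) stop("need at least 2 lines")
  if (stats::var(p$value) == 0) {
    return(structure(list(
      blups = stats::setNames(rep(p$value[1], length(lines)), lines),
      varcomp = c(line = 0, rep = 0, residual = 0)
    ), class = "line_blups"))
  }
  has_rep <- length(unique(p$rep)) > 1
  fml <- if (has_rep) value ~ (1 | line) + (1 | rep) else value ~ (1 | line)
  fit <- suppressMessages(lme4::lmer(fml, data = p))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  if (getv("line") == 0) {
    warning("zero between-line variance: all BLUPs equal the grand mean")
  }
  mu <- lme4::fixef(fit)[["(Intercept)"]]
  re <- lme4::ranef(fit)$line
  blups <- stats::setNames(mu + re[[1]], rownames(re))
  blups <- blups[as.character(lines)]
  structure(list(
    blups = blups,
    varcomp = c(line = getv("line"), rep = getv("rep"),
                residual = getv("Residual"))
  ), class = "line_blups")
}

#' VanRaden genomic relationship (kinship) matrix
#'
#' \code{K = W W' / (2 sum p_j (1 - p_j))} with \code{W} the
#' allele-frequency-centred dosage matrix (dosage minus \code{2 p_j}).
#' Monomorphic SNPs carry no information and are excluded with a warning.
#'
#' @param g a filtered, fully imputed \code{genotype_matrix}.
#' @return An \code{n x n} symmetric positive semidefinite matrix with the
#'   scaling constant attached as attribute \code{"scale"}.
#' @export
vanraden_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"), !anyNA(g$dosages))
  p <- colMeans(g$dosages) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from kinship")
  }
  dos <- g$dosages[, !mono, drop = FALSE]
  p <- p[!mono]
  W <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(g$line_id, g$line_id)
  attr(K, "scale") <- denom
  K
}

# Profiled REML for y = X b + u + e with Var(u) = Vg * M, Var(e) = Ve * I,
# given the spectral decomposition M = U diag(d) U'. Returns the variance
# ratio delta = Ve/Vg by grid search plus local refinement; on a flat
# likelihood (M proportional to I) ties break toward the largest delta,
# i.e. Vg -> 0.
.reml_eigen <- function(y, X, U, d, log_delta_range = c(-10, 10), n_grid = 81) {
  n <- length(y); p <- ncol(X)
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X)
  crit <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xtil * w, Xtil)
    beta <- solve(XtWX, crossprod(Xtil * w, ytil))
    r <- ytil - drop(Xtil %*% beta)
    rss <- sum(w * r^2)
    ll <- -0.5 * ((n - p) * log(rss) + sum(log(d + delta)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), beta = beta, rss = rss)
  }
  grid <- seq(log_delta_range[1], log_delta_range[2], length.out = n_grid)
  lls <- vapply(grid, function(ld) crit(ld)$ll, numeric(1))
  best <- max(lls)
  i <- max(which(lls >= best - 1e-8))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  opt <- stats::optimize(function(ld) crit(ld)$ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  log_delta <- if (opt$objective >= lls[i] - 1e-10) opt$maximum else grid[i]
  res <- crit(log_delta)
  Vg <- res$rss / (n - p)
  list(delta = exp(log_delta), Vg = Vg, Ve = exp(log_delta) * Vg,
       beta = drop(res$beta), loglik = res$ll, ytil = ytil, Xtil = Xtil)
}

#' Fit the marker-free (null) mixed linear model
#'
#' REML fit of \code{y = mu + u + e} with \code{Var(u) = Vg * 2K} and
#' \code{Var(e) = Ve * I}, via a single spectral decomposition of \code{2K}
#' and profiled optimisation over the variance ratio. The decomposition is
#' cached for the marker scan.
#'
#' @param y a \code{line_blups} object or numeric vector of line values.
#' @param K kinship matrix (symmetric PSD to numerical tolerance).
#' @return A list of class \code{mlm_fit} with \code{Vg}, \code{Ve},
#'   \code{mu}, and the cached decomposition.
#' @export
fit_null_mlm <- function(y, K) {
  if (inherits(y, "line_blups")) y <- y$blups
  y <- as.numeric(y)
  K <- as.matrix(K)
  stopifnot(length(y) == nrow(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  eig <- eigen(2 * K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop("K is not positive semidefinite")
  }
  d <- pmax(eig$values, 0)
  X <- matrix(1, length(y), 1)
  res <- .reml_eigen(y, X, eig$vectors, d)
  structure(list(Vg = res$Vg, Ve = res$Ve, mu = res$beta[1],
                 delta = res$delta, U = eig$vectors, d = d, y = y),
            class = "mlm_fit")
}

#' Genome-wide marker scan under the mixed linear model
#'
#' Tests each SNP as a fixed effect by generalized least squares with the
#' covariance structure \code{Vg * 2K + Ve * I} held at the null-model REML
#' estimates (population parameters previously determined). The per-marker
#' residual scale is re-estimated on the fixed covariance shape, so with
#' \code{Vg = 0} and \code{K} proportional to the identity the test reduces
#' exactly to the ordinary least-squares t-test. Per-SNP variance explained
#' (\code{r2}) is the R-squared of the simple general linear model of the
#' trait on that SNP. Monomorphic SNPs are reported with \code{p = 1} and
#' flagged. Benjamini-Hochberg q-values are included.
#'
#' @param fit a [fit_null_mlm()] object.
#' @param g the \code{genotype_matrix} used for the kinship.
#' @return A data frame of class \code{snp_association} with columns
#'   \code{snp}, \code{index}, \code{chrom}, \code{pos}, \code{maf},
#'   \code{effect}, \code{p_value}, \code{q_value}, \code{r2},
#'   \code{monomorphic}.
#' @export
scan_markers <- function(fit, g) {
  stopifnot(inherits(fit, "mlm_fit"), inherits(g, "genotype_matrix"))
  dos <- g$dosages
  stopifnot(nrow(dos) == length(fit$y))
  n <- nrow(dos); m <- ncol(dos)
  pfreq0 <- colMeans(dos) / 2
  # a (numerically) constant response carries no association information:
  # report p = 1 everywhere rather than testing floating-point noise
  if (stats::var(fit$y) <= (1e-8 * (abs(mean(fit$y)) + 1))^2) {
    warning("response is constant: all associations reported with p = 1")
    out <- data.frame(
      snp = g$snp_id, index = seq_len(m), chrom = g$chrom, pos = g$pos,
      maf = pmin(pfreq0, 1 - pfreq0), effect = 0, p_value = 1, q_value = 1,
      r2 = 0, monomorphic = apply(dos, 2, function(x) length(unique(x)) == 1),
      row.names = NULL
    )
    class(out) <- c("snp_association", "data.frame")
    return(out)
  }
  w <- 1 / (fit$Vg * fit$d + fit$Ve)
  U <- fit$U
  u1 <- drop(crossprod(U, rep(1, n)))
  uy <- drop(crossprod(U, fit$y))
  UX <- crossprod(U, dos)

  a11 <- sum(w * u1 * u1)
  b1 <- sum(w * u1 * uy)
  syy <- sum(w * uy * uy)
  a12 <- drop(crossprod(UX, w * u1))
  a22 <- colSums(UX^2 * w)
  b2 <- drop(crossprod(UX, w * uy))

  det <- a11 * a22 - a12^2
  mono <- apply(dos, 2, function(x) length(unique(x)) == 1)
  det_safe <- ifelse(mono | det <= 0, NA, det)
  alpha <- (a11 * b2 - a12 * b1) / det_safe
  beta0 <- (a22 * b1 - a12 * b2) / det_safe
  rss <- syy - beta0 * b1 - alpha * b2
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sigma2 * a11 / det_safe)
  tstat <- alpha / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[mono | !is.finite(p) | sigma2 <= 0] <- 1
  alpha[mono] <- 0

  r2 <- suppressWarnings(stats::cor(fit$y, dos))^2
  r2 <- as.vector(r2); r2[mono | !is.finite(r2)] <- 0
  pfreq <- colMeans(dos) / 2
  out <- data.frame(
    snp = g$snp_id, index = seq_len(m), chrom = g$chrom, pos = g$pos,
    maf = pmin(pfreq, 1 - pfreq), effect = alpha, p_value = p,
    q_value = stats::p.adjust(p, method = "BH"), r2 = r2,
    monomorphic = mono, row.names = NULL
  )
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH procedure at level \code{q}: q-values via
#' \code{p.adjust(method = "BH")}; a test is significant iff its q-value is
#' at most \code{q}.
#'
#' @param pvals numeric p-values in \code{[0, 1]}.
#' @param q FDR level (default 0.05).
#' @return List with logical \code{significant} and numeric \code{q_value}.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(list(significant = logical(0), q_value = numeric(0)))
  }
  stopifnot(all(pvals >= 0 & pvals <= 1))
  qv <- stats::p.adjust(pvals, method = "BH")
  list(significant = qv <= q, q_value = qv)
}

#' Pairwise LD between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors (composite LD; for fully
#' inbred lines this equals the haplotype-level r-squared).
#'
#' @param g a \code{genotype_matrix}.
#' @param snp_i,snp_j SNP column indices.
#' @return r-squared in \code{[0, 1]}.
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  x <- g$dosages[, snp_i]; y <- g$dosages[, snp_j]
  ok <- !is.na(x) & !is.na(y)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    stop("LD undefined for a monomorphic SNP")
  }
  stats::cor(x[ok], y[ok])^2
}

#' Greedy LD clumping of significant associations
#'
#' Repeatedly takes the lowest-p remaining significant SNP as a peak and
#' absorbs all remaining significant SNPs on the same chromosome with
#' \code{r2 > r2_threshold} to that peak. Cross-chromosome pairs are never
#' merged. Clusters are returned ordered by peak chromosome and position.
#'
#' @param assocs rows of a [scan_markers()] table, already restricted to
#'   FDR-significant SNPs (columns \code{index}, \code{chrom}, \code{pos},
#'   \code{p_value} required).
#' @param g the \code{genotype_matrix}.
#' @param r2_threshold LD threshold (default 0.20; members satisfy
#'   \code{r2 > threshold}).
#' @return A list of class \code{qtl_clusters}; each element has \code{peak}
#'   (one-row data frame), \code{members} (data frame of all member rows) and
#'   \code{r2_to_peak}.
#' @export
clump_loci <- function(assocs, g, r2_threshold = 0.20) {
  assocs <- as.data.frame(assocs)
  clusters <- list()
  remaining <- assocs[order(assocs$p_value), , drop = FALSE]
  while (nrow(remaining) > 0) {
    peak <- remaining[1, , drop = FALSE]
    same_chr <- remaining$chrom == peak$chrom
    r2 <- rep(NA_real_, nrow(remaining))
    r2[1] <- 1
    for (i in which(same_chr & seq_len(nrow(remaining)) > 1)) {
      r2[i] <- ld_r2(g, peak$index, remaining$index[i])
    }
    in_clump <- same_chr & !is.na(r2) & r2 > r2_threshold
    in_clump[1] <- TRUE
    clusters[[length(clusters) + 1]] <- list(
      peak = peak,
      members = remaining[in_clump, , drop = FALSE],
      r2_to_peak = r2[in_clump]
    )
    remaining <- remaining[!in_clump, , drop = FALSE]
  }
  ord <- order(vapply(clusters, function(cl) cl$peak$chrom, numeric(1)),
               vapply(clusters, function(cl) cl$peak$pos, numeric(1)))
  structure(clusters[ord], class = "qtl_clusters")
}

#' Two-locus allelic phase summary
#'
#' For fully inbred lines, classifies each line as carrying the two loci in
#' coupling (both favorable alleles or both unfavorable) or repulsion (one of
#' each), and counts the favorable-favorable combination. Heterozygous calls
#' are excluded with a warning; lines missing at either locus are excluded
#' from all denominators.
#'
#' @param g a \code{genotype_matrix}.
#' @param locus_a,locus_b SNP column indices.
#' @param favorable_a,favorable_b the favorable homozygous dosage (0 or 2) at
#'   each locus.
#' @return A list of class \code{phase_summary}: \code{n} informative lines,
#'   \code{coupling}/\code{repulsion} counts and fractions, and
#'   \code{favorable} (favorable-favorable) count and fraction.
#' @export
classify_phase <- function(g, locus_a, locus_b, favorable_a = 2,
                           favorable_b = 2) {
  stopifnot(favorable_a %in% c(0, 2), favorable_b %in% c(0, 2))
  a <- g$dosages[, locus_a]; b <- g$dosages[, locus_b]
  het <- (!is.na(a) & a == 1) | (!is.na(b) & b == 1)
  if (any(het)) {
    warning(sum(het), " line(s) with heterozygous calls excluded")
  }
  ok <- !is.na(a) & !is.na(b) & !het
  if (!any(ok)) stop("no informative lines at this locus pair")
  fa <- a[ok] == favorable_a
  fb <- b[ok] == favorable_b
  coupling <- fa == fb
  n <- sum(ok)
  structure(list(
    n = n,
    coupling = sum(coupling), coupling_frac = mean(coupling),
    repulsion = sum(!coupling), repulsion_frac = mean(!coupling),
    favorable = sum(fa & fb), favorable_frac = mean(fa & fb)
  ), class = "phase_summary")
}
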