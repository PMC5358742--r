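test_that("SNP QC applies missing-rate filter, mode imputation, MAF filter in order", {
  dos <- cbind(
    c(0, 2, 0, 2, 0, 2, 0, 2, 0, 2),       # clean, MAF 0.5
    c(NA, NA, 0, 2, 0, 2, 0, 2, 0, 2),     # 20% missing -> removed
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2),       # MAF 0.10 -> kept
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # MAF 0 -> removed
    c(NA, 0, 0, 0, 0, 2, 2, 0, 0, 2)       # 10% missing -> imputed to mode 0
  )
  g <- filter_snps(toy_geno(dos))
  expect_equal(ncol(g$dosages), 3)
  expect_equal(g$snp_id, c("s1", "s3", "s5"))
  expect_false(anyNA(g$dosages))
  expect_equal(g$dosages[1, 3], 0)  # imputed modal genotype
  expect_error(filter_snps(toy_geno(dos[, 4, drop = FALSE])), "MAF filter")
})

test_that("identical observations give identical BLUPs; rep labels exchangeable", {
  p <- data.frame(line = rep(c("a", "b", "c"), each = 4),
                  rep = rep(1:4, 3), value = 7)
  bl <- compute_blups(p)
  expect_equal(unname(bl$blups), rep(7, 3))

  set.seed(1)
  p2 <- data.frame(line = rep(sprintf("L%02d", 1:12), each = 4),
                   rep = rep(1:4, 12))
  p2$value <- rnorm(12)[as.integer(factor(p2$line))] + rnorm(48, 0, 0.5)
  b1 <- compute_blups(p2)
  p3 <- p2; p3$rep <- c(2, 3, 4, 1)[p3$rep]
  b2 <- compute_blups(p3)
  expect_equal(b1$blups, b2$blups, tolerance = 1e-6)
})

test_that("balanced-design BLUPs equal the closed-form shrinkage of line means", {
  set.seed(42)
  n_l <- 15; r <- 4
  p <- data.frame(line = rep(sprintf("L%02d", 1:n_l), each = r),
                  rep = rep(1:r, n_l))
  p$value <- 10 + rnorm(n_l, 0, 1)[as.integer(factor(p$line))] + rnorm(n_l * r, 0, 2)
  bl <- compute_blups(p)
  sg2 <- bl$varcomp[["line"]]; se2 <- bl$varcomp[["residual"]]
  mu <- mean(p$value)
  ym <- as.numeric(tapply(p$value, p$line, mean)[names(bl$blups)])
  shrink <- r * sg2 / (r * sg2 + se2)
  expect_equal(unname(bl$blups), mu + shrink * (ym - mu), tolerance = 1e-6)
  # shrinkage toward the grand mean
  expect_true(all(abs(bl$blups - mu) <= abs(ym - mu) + 1e-10))
})

test_that("VanRaden kinship matches hand computation and is PSD", {
  dos <- rbind(c(0, 2), c(2, 0), c(2, 2))
  g <- toy_geno(dos)
  K <- vanraden_kinship(g)
  p <- c(4 / 6, 4 / 6)
  W <- sweep(dos, 2, 2 * p)
  K_hand <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  expect_equal(unname(K[, ]), unname(K_hand), tolerance = 1e-12)
  expect_equal(K, t(K))

  # identical lines: identical rows, off-diagonal equals diagonal
  g2 <- toy_geno(rbind(c(0, 2, 2), c(0, 2, 2), c(2, 0, 0)))
  K2 <- vanraden_kinship(g2)
  expect_equal(K2[1, ], K2[2, ], ignore_attr = TRUE)
  expect_equal(K2[1, 2], K2[1, 1])

  g3 <- simulate_genotypes(40, 80, seed = 1)
  K3 <- vanraden_kinship(g3)
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  expect_warning(vanraden_kinship(toy_geno(cbind(c(0, 2), c(2, 2)))),
                 "monomorphic")
})

test_that("null REML matches a brute-force grid oracle on n = 10", {
  set.seed(3)
  n <- 10
  g <- simulate_genotypes(n, 40, seed = 11)
  K <- suppressWarnings(vanraden_kinship(g))  # tiny panel: monomorphs expected
  y <- as.numeric(chol(2 * K + 0.5 * diag(n)) %*% rnorm(n))
  fit <- fit_null_mlm(y, K)

  # independent oracle: direct dense-matrix profiled REML on a log10 grid
  X <- matrix(1, n, 1)
  crit <- function(delta) {
    V0 <- 2 * K + delta * diag(n)
    Vi <- solve(V0)
    beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    drop((n - 1) * log(rss) + determinant(V0)$modulus +
           determinant(t(X) %*% Vi %*% X)$modulus)
  }
  grid <- 10^seq(-3, 3, by = 0.01)
  vals <- vapply(grid, crit, numeric(1))
  delta_star <- grid[which.min(vals)]
  expect_equal(log10(fit$Ve / fit$Vg), log10(delta_star), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("K proportional to identity attributes variance to noise", {
  vg_share <- replicate(20, {
    y <- rnorm(40)
    fit <- fit_null_mlm(y, diag(40) / 2)
    fit$Vg / var(y)
  })
  expect_lt(median(vg_share), 0.05)
})

test_that("strong kinship-correlated signal yields a high heritability estimate", {
  set.seed(8)
  g <- simulate_genotypes(200, 400, seed = 8)
  ph <- simulate_phenotypes(g, trait_architecture(h2 = 0.9), seed = 9)
  y <- tapply(ph$value, ph$line, mean)[g$line_id]
  fit <- fit_null_mlm(y, vanraden_kinship(g))
  # heritable share on the observation scale: Vg scaled by mean diag of 2K
  vg_eff <- fit$Vg * mean(diag(2 * vanraden_kinship(g)))
  expect_gt(vg_eff / (vg_eff + fit$Ve), 0.5)
})

test_that("kinship validation rejects asymmetric and indefinite matrices", {
  y <- rnorm(5)
  M <- matrix(rnorm(25), 5, 5)
  expect_error(fit_null_mlm(y, M), "symmetric")
  N <- diag(5); N[1, 1] <- -2
  expect_error(fit_null_mlm(y, N), "positive semidefinite")
})

test_that("marker scan reduces exactly to OLS when Vg = 0 and K is identity-like", {
  set.seed(21)
  n <- 60
  g <- simulate_genotypes(n, 50, seed = 21)
  y <- rnorm(n)
  fit <- fit_null_mlm(y, diag(n) / 2)
  fit$Vg <- 0; fit$Ve <- 1
  sc <- scan_markers(fit, g)
  p_ols <- vapply(seq_len(50), function(j) {
    x <- g$dosages[, j]
    if (var(x) == 0) return(1)
    summary(lm(y ~ x))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(sc$p_value, p_ols, tolerance = 1e-10)
})

test_that("monomorphic SNPs are reported flagged with p = 1", {
  dos <- cbind(rep(2, 20), rbinom(20, 1, 0.5) * 2)
  y <- rnorm(20)
  fit <- fit_null_mlm(y, diag(20) / 2)
  sc <- scan_markers(fit, toy_geno(dos))
  expect_true(sc$monomorphic[1])
  expect_equal(sc$p_value[1], 1)
  expect_equal(sc$effect[1], 0)
})

test_that("permuted phenotypes yield uniform p-values", {
  set.seed(5)
  g <- simulate_genotypes(120, 300, seed = 5)
  ph <- simulate_phenotypes(g, trait_architecture(h2 = 0.5), seed = 6)
  y0 <- tapply(ph$value, ph$line, mean)[g$line_id]
  K <- vanraden_kinship(g)
  ok <- replicate(20, {
    y <- sample(as.numeric(y0))
    fit <- fit_null_mlm(y, K)
    sc <- scan_markers(fit, g)
    suppressWarnings(ks.test(sc$p_value, "punif")$p.value) > 0.01
  })
  expect_gte(sum(ok), 18)
})

test_that("BH step-up flags match the definition on hand lists", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.2), q = 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$q_value, p.adjust(c(0.01, 0.02, 0.03, 0.2), "BH"))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_true(all(bh_fdr(rep(1e-6, 100))$significant))
  expect_equal(bh_fdr(numeric(0))$significant, logical(0))
})

test_that("LD r2 behaves on identical, orthogonal and anti-correlated vectors", {
  g <- toy_geno(cbind(c(0, 2, 0, 2), c(0, 2, 0, 2), c(0, 0, 2, 2),
                      c(2, 0, 2, 0), c(2, 2, 2, 2)))
  expect_equal(ld_r2(g, 1, 2), 1)
  expect_equal(ld_r2(g, 1, 3), 0)
  expect_equal(ld_r2(g, 1, 4), 1)  # sign-invariance
  expect_error(ld_r2(g, 1, 5), "monomorphic")
})

test_that("greedy clumping groups linked SNPs around the lowest-p peak", {
  set.seed(13)
  x1 <- rep(c(0, 2), each = 20)
  x2 <- x1; flip <- sample(40, 6); x2[flip] <- 2 - x2[flip]  # linked to x1
  x3 <- rep(c(0, 2), times = 20)                             # unlinked
  g <- toy_geno(cbind(x1, x2, x3))
  expect_gt(ld_r2(g, 1, 2), 0.2)
  expect_lt(ld_r2(g, 1, 3), 0.2)
  expect_lt(ld_r2(g, 2, 3), 0.2)
  assocs <- data.frame(snp = c("s1", "s2", "s3"), index = 1:3,
                       chrom = c(1, 1, 1), pos = c(100, 200, 300),
                       p_value = c(1e-8, 1e-6, 1e-5))
  cl <- clump_loci(assocs, g)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$peak$index, 1)
  expect_equal(sort(cl[[1]]$members$index), c(1, 2))
  expect_equal(cl[[2]]$peak$index, 3)

  # single significant SNP: its own cluster and peak
  cl1 <- clump_loci(assocs[1, ], g)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$members$index, 1)

  # same chromosome but weak LD (r2 ~ 0.1): two separate clusters
  cl2 <- clump_loci(assocs[c(1, 3), ], g)
  expect_length(cl2, 2)

  # different chromosomes are never merged even at r2 = 1
  g2 <- toy_geno(cbind(x1, x1), chrom = c(1L, 2L))
  a2 <- data.frame(snp = c("s1", "s2"), index = 1:2, chrom = c(1, 2),
                   pos = c(1, 1), p_value = c(1e-9, 1e-8))
  expect_length(clump_loci(a2, g2), 2)
})

test_that("cluster peaks are pairwise unlinked or on different chromosomes", {
  set.seed(17)
  g <- simulate_genotypes(200, 300, n_chrom = 3, ld_rho = 0.9, seed = 17)
  ph <- simulate_phenotypes(
    g, trait_architecture(qtl = data.frame(snp = c(50, 250), r2 = c(0.2, 0.15)),
                          h2 = 0.8), seed = 18)
  y <- tapply(ph$value, ph$line, mean)[g$line_id]
  fit <- fit_null_mlm(y, vanraden_kinship(g))
  sc <- scan_markers(fit, g)
  sig <- sc[sc$q_value <= 0.05, ]
  if (nrow(sig) >= 2) {
    cl <- clump_loci(sig, g)
    peaks <- do.call(rbind, lapply(cl, `[[`, "peak"))
    if (nrow(peaks) >= 2) {
      for (i in 1:(nrow(peaks) - 1)) for (j in (i + 1):nrow(peaks)) {
        same <- peaks$chrom[i] == peaks$chrom[j]
        expect_true(!same || ld_r2(g, peaks$index[i], peaks$index[j]) <= 0.2)
      }
    }
  }
})

test_that("two-locus phase classification counts coupling and favorable lines", {
  # allele pairs: (F,F), (U,U), (F,U), (F,F) with favorable dosage 2
  g <- toy_geno(cbind(c(2, 0, 2, 2), c(2, 0, 0, 2)))
  ps <- classify_phase(g, 1, 2)
  expect_equal(ps$n, 4)
  expect_equal(ps$coupling, 3)
  expect_equal(ps$coupling_frac, 0.75)
  expect_equal(ps$repulsion, 1)
  expect_equal(ps$favorable, 2)
  expect_equal(ps$favorable_frac, 0.5)
  expect_equal(ps$coupling + ps$repulsion, ps$n)

  all_f <- toy_geno(cbind(c(2, 2, 2), c(2, 2, 2)))
  ps2 <- classify_phase(all_f, 1, 2)
  expect_equal(ps2$coupling_frac, 1)
  expect_equal(ps2$favorable_frac, 1)

  g_het <- toy_geno(cbind(c(2, 1, 0), c(2, 2, 0)))
  expect_warning(ps3 <- classify_phase(g_het, 1, 2), "heterozygous")
  expect_equal(ps3$n, 2)

  g_na <- toy_geno(cbind(c(NA, NA, NA), c(2, 0, 2)))
  expect_error(classify_phase(g_na, 1, 2), "no informative lines")
})
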