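test_that("constant markers give u = 0 and beta equal to least squares", {
  set.seed(1)
  dos <- matrix(2, 20, 10)
  y <- rnorm(20)
  x_fix <- rbinom(20, 1, 0.5) * 2
  d <- gp_design(cbind(dos), y, fixed_snps = NULL, spad = x_fix)
  fit <- fit_rrblup(d)
  expect_equal(fit$u, rep(0, 10))
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ x_fix))), tolerance = 1e-8)
})

test_that("fixed-lambda solution equals the closed-form ridge / MME solve", {
  check_mme <- function(n, m, lambda, seed) {
    set.seed(seed)
    dos <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
    y <- rnorm(n)
    d <- gp_design(dos, y)
    fit <- fit_rrblup(d, lambda = lambda)
    Z <- scale(dos, center = TRUE, scale = FALSE)
    X <- matrix(1, n, 1)
    # mixed-model equations at fixed lambda
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + lambda * diag(m)))
    sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
    expect_equal(unname(fit$beta), sol[1], tolerance = 1e-8)
    expect_equal(fit$u, sol[-1], tolerance = 1e-8, ignore_attr = TRUE)
  }
  check_mme(3, 2, 1, seed = 2)      # tiny instance
  check_mme(50, 200, 2.5, seed = 3) # overparameterised instance
})

test_that("RR-BLUP genomic values equal GBLUP at matched variance components", {
  set.seed(4)
  n <- 40; m <- 150
  g <- simulate_genotypes(n, m, seed = 4)
  ph <- simulate_phenotypes(g, trait_architecture(h2 = 0.6), seed = 5)
  y <- as.numeric(tapply(ph$value, ph$line, mean)[g$line_id])
  d <- gp_design(g, y)
  fit <- fit_rrblup(d)
  Z <- sweep(g$dosages, 2, fit$centers)
  G <- tcrossprod(Z)
  r <- y - fit$beta[["intercept"]]
  gblup <- G %*% solve(G + fit$lambda * diag(n), r)
  expect_equal(drop(Z %*% fit$u), drop(gblup), tolerance = 1e-6)
})

test_that("rank-deficient fixed designs are rejected naming the columns", {
  g <- simulate_genotypes(30, 20, seed = 6)
  y <- rnorm(30)
  expect_error(gp_design(g, y, spad = rep(1, 30)), "spad")
  expect_error(gp_design(g, y, fixed_snps = c(1, 1)), "rank deficient")
})

test_that("prediction is consistent, linear, and validates dimensions", {
  set.seed(7)
  g <- simulate_genotypes(30, 40, seed = 7)
  y <- rnorm(30)
  d <- gp_design(g, y)
  fit <- fit_rrblup(d)
  # training data reproduce the fitted values
  expect_equal(predict_gebv(fit, d$X, d$dosages),
               drop(d$X %*% fit$beta +
                      sweep(d$dosages, 2, fit$centers) %*% fit$u))
  # a line at the training marker means predicts X beta exactly
  avg <- matrix(fit$centers, 1)
  expect_equal(predict_gebv(fit, matrix(1, 1, 1), avg),
               unname(fit$beta[["intercept"]]))
  # doubling one marker's deviation doubles its contribution
  z1 <- avg; z1[1, 5] <- fit$centers[5] + 1
  z2 <- avg; z2[1, 5] <- fit$centers[5] + 2
  d1 <- predict_gebv(fit, matrix(1, 1, 1), z1) - fit$beta[["intercept"]]
  d2 <- predict_gebv(fit, matrix(1, 1, 1), z2) - fit$beta[["intercept"]]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
  expect_error(predict_gebv(fit, matrix(1, 1, 1), avg[, 1:10, drop = FALSE]),
               "marker count")
})

test_that("cross-validation recovers a perfect linear signal and is seeded", {
  set.seed(8)
  g <- simulate_genotypes(60, 30, seed = 8)
  y <- 2 + 0.7 * g$dosages[, 3]
  d <- gp_design(g, y)
  cv <- cross_validate(d, k = 10, seed = 3)
  expect_gt(cv$accuracy, 0.99)
  cv2 <- cross_validate(d, k = 10, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$accuracy, cv2$accuracy)
  expect_error(cross_validate(d, k = 100, seed = 1), "k must not exceed")
  expect_equal(sort(unique(cv$fold)), 1:10)
})

test_that("heritability-zero panels give near-zero mean CV accuracy", {
  accs <- replicate(20, {
    seed <- sample.int(1e6, 1)
    g <- simulate_genotypes(100, 60, seed = seed)
    ph <- simulate_phenotypes(g, trait_architecture(h2 = 0), seed = seed + 1)
    y <- tapply(ph$value, ph$line, mean)[g$line_id]
    # per-fold accuracy: held-out values are independent of the fold's model,
    # so its null expectation is 0 (the pooled correlation carries the usual
    # negative cross-validation bias from fold-mean intercepts)
    mean(cross_validate(gp_design(g, as.numeric(y)), k = 10, seed = seed)$per_fold)
  })
  expect_lt(abs(mean(accs)), 0.1)
})

test_that("linked opposite-effect QTL show adjacent opposite-sign effect peaks", {
  set.seed(9)
  g <- simulate_genotypes(300, 400, n_chrom = 2, ld_rho = 0.9, seed = 9)
  arch <- trait_architecture(
    qtl = data.frame(snp = c(100, 103), effect = c(0.8, -0.8)), h2 = 0.9)
  ph <- simulate_phenotypes(g, arch, seed = 10)
  y <- as.numeric(tapply(ph$value, ph$line, mean)[g$line_id])
  fit <- fit_rrblup(gp_design(g, y))
  prof <- marker_effect_profile(fit)
  expect_equal(names(prof), c("snp", "chrom", "pos", "effect"))
  # the two largest-magnitude effects sit near the planted pair, opposite signs
  top <- order(abs(prof$effect), decreasing = TRUE)[1:2]
  idx <- match(prof$snp[top], fit$map$snp)
  expect_true(all(abs(idx - 101.5) <= 8))
  expect_equal(prod(sign(prof$effect[top])), -1)
})

test_that("permuting SNP order permutes the effect track identically", {
  set.seed(11)
  g <- simulate_genotypes(40, 30, seed = 11)
  y <- rnorm(40)
  fit <- fit_rrblup(gp_design(g, y))
  perm <- sample(30)
  g2 <- structure(list(dosages = g$dosages[, perm], chrom = g$chrom[perm],
                       pos = g$pos[perm], snp_id = g$snp_id[perm],
                       line_id = g$line_id), class = "genotype_matrix")
  fit2 <- fit_rrblup(gp_design(g2, y))
  p1 <- marker_effect_profile(fit)
  p2 <- marker_effect_profile(fit2)
  expect_equal(p2$effect[match(p1$snp, p2$snp)], p1$effect, tolerance = 1e-6)
})

test_that("null-panel marker effects show no extreme outliers", {
  n_ok <- sum(replicate(20, {
    seed <- sample.int(1e6, 1)
    g <- simulate_genotypes(50, 100, seed = seed)
    ph <- simulate_phenotypes(g, trait_architecture(h2 = 0), seed = seed + 1)
    y <- as.numeric(tapply(ph$value, ph$line, mean)[g$line_id])
    fit <- fit_rrblup(gp_design(g, y))
    u <- fit$u
    z <- (u - mean(u)) / (sd(u) + 1e-12)
    bonf <- qnorm(1 - 0.025 / length(u))
    all(abs(z) <= bonf)
  }))
  expect_gte(n_ok, 18)
})
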