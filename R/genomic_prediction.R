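#' Design for RR-BLUP genomic prediction
#'
#' Assembles the fixed design \code{X} (intercept, optional major-QTL dosage
#' columns, optional SPAD-like covariate) and the random marker design (raw
#' dosages; they are centred with training means at fit time) for
#' [fit_rrblup()] and [cross_validate()].
#'
#' @param g a \code{genotype_matrix} (no missing dosages).
#' @param y a \code{line_blups} object or numeric vector of trait values.
#' @param fixed_snps integer indices of SNPs modelled as fixed effects.
#' @param spad optional numeric line-level covariate (e.g. SPAD surrogate).
#' @return A list of class \code{gp_design} with \code{X}, \code{dosages},
#'   \code{y}. Errors if \code{X} is rank deficient, naming the collinear
#'   columns.
#' @export
gp_design <- function(g, y, fixed_snps = NULL, spad = NULL) {
  if (inherits(y, "line_blups")) y <- y$blups
  y <- as.numeric(y)
  dos <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  stopifnot(!anyNA(dos), nrow(dos) == length(y))
  X <- matrix(1, nrow(dos), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(fixed_snps)) {
    fx <- dos[, fixed_snps, drop = FALSE]
    colnames(fx) <- paste0("snp", fixed_snps)
    X <- cbind(X, fx)
  }
  if (!is.null(spad)) {
    stopifnot(length(spad) == length(y))
    X <- cbind(X, spad = as.numeric(spad))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, dosages = dos, y = y,
                 map = if (inherits(g, "genotype_matrix")) {
                   data.frame(snp = g$snp_id, chrom = g$chrom, pos = g$pos)
                 } else NULL),
            class = "gp_design")
}

#' Fit RR-BLUP with fixed covariates
#'
#' Ridge-regression BLUP: \code{y = X beta + Z u + e} with
#' \code{Var(u) = sigma_u^2 I} (all markers share one variance) and
#' \code{Var(e) = sigma_e^2 I}; \code{Z} is the column-centred dosage matrix.
#' The variance ratio \code{lambda = sigma_e^2 / sigma_u^2} is estimated by
#' REML on the spectral decomposition of \code{Z Z'} unless supplied, in
#' which case the solution is the exact closed form
#' \code{u = Z'(Z Z' + lambda I)^{-1} (y - X beta)} with \code{beta} by
#' generalized least squares.
#'
#' @param design a [gp_design()].
#' @param lambda optional fixed variance ratio; \code{NULL} (default) for
#'   REML estimation.
#' @return A list of class \code{rrblup_fit}: \code{beta} (named),
#'   \code{u} (marker effects), \code{sigma_u2}, \code{sigma_e2},
#'   \code{lambda}, \code{centers} (training marker means), \code{map}.
#' @export
fit_rrblup <- function(design, lambda = NULL) {
  stopifnot(inherits(design, "gp_design"))
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X)
  if (n < 2 * p) stop("need at least 2 x ncol(X) observations")
  centers <- colMeans(design$dosages)
  Z <- sweep(design$dosages, 2, centers)
  if (all(abs(Z) < 1e-12)) {
    beta <- qr.coef(qr(X), y)
    return(structure(list(beta = beta, u = rep(0, ncol(Z)),
                          sigma_u2 = 0, sigma_e2 = stats::var(y - X %*% beta),
                          lambda = Inf, centers = centers, map = design$map),
                     class = "rrblup_fit"))
  }
  G <- tcrossprod(Z)
  eig <- eigen(G, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  if (is.null(lambda)) {
    # REML over log(delta) with delta = sigma_e2/sigma_u2; Z Z' spectrum spans
    # a wide range, so centre the search grid on its mean eigenvalue
    scale_d <- mean(d[d > 0])
    res <- .reml_eigen(y, X, U, d,
                       log_delta_range = log(scale_d) + c(-12, 12),
                       n_grid = 121)
    lambda <- res$delta
    beta <- res$beta
    sigma_u2 <- res$Vg
    sigma_e2 <- res$Ve
  } else {
    w <- 1 / (d + lambda)
    ytil <- drop(crossprod(U, y)); Xtil <- crossprod(U, X)
    XtWX <- crossprod(Xtil * w, Xtil)
    beta <- drop(solve(XtWX, crossprod(Xtil * w, ytil)))
    rss <- sum(w * (ytil - drop(Xtil %*% beta))^2)
    sigma_u2 <- rss / (n - p)
    sigma_e2 <- lambda * sigma_u2
  }
  w <- 1 / (d + lambda)
  r <- y - drop(X %*% beta)
  u <- drop(crossprod(Z, U %*% (w * drop(crossprod(U, r)))))
  structure(list(beta = stats::setNames(drop(beta), colnames(X)), u = u,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, lambda = lambda,
                 centers = centers, map = design$map),
            class = "rrblup_fit")
}

#' Genomic estimated breeding values for new lines
#'
#' \code{yhat = X_new beta + Z_new u}, where \code{Z_new} is the new lines'
#' raw dosage matrix centred with the training marker means.
#'
#' @param fit an [fit_rrblup()] object.
#' @param X_new fixed design of the new lines (same columns as training).
#' @param dosages_new raw dosage matrix of the new lines.
#' @return Numeric predictions.
#' @export
predict_gebv <- function(fit, X_new, dosages_new) {
  stopifnot(inherits(fit, "rrblup_fit"))
  X_new <- as.matrix(X_new)
  dosages_new <- as.matrix(dosages_new)
  if (ncol(X_new) != length(fit$beta)) stop("fixed design column mismatch")
  if (ncol(dosages_new) != length(fit$u)) stop("marker count mismatch")
  Zn <- sweep(dosages_new, 2, fit$centers)
  drop(X_new %*% fit$beta + Zn %*% fit$u)
}

#' k-fold cross-validated genomic prediction accuracy
#'
#' Lines are shuffled into \code{k} folds by seed; the RR-BLUP model is refit
#' on each training split and used to predict the held-out lines. Fixed
#' covariates of held-out lines (QTL genotype, SPAD surrogate) are used at
#' prediction time: both are observable without the phenotype being
#' predicted, though this does inflate accuracy relative to genotype-only
#' prediction. Accuracy is the Pearson correlation between observed values
#' and pooled out-of-fold predictions.
#'
#' @param design a [gp_design()].
#' @param k number of folds (default 10); must not exceed the line count.
#' @param seed integer seed for the fold shuffle.
#' @return A list of class \code{cv_result}: \code{fold} assignment,
#'   \code{predicted}, \code{accuracy}, \code{per_fold} accuracies,
#'   \code{seed}.
#' @export
cross_validate <- function(design, k = 10, seed = 1L) {
  stopifnot(inherits(design, "gp_design"))
  n <- length(design$y)
  if (k > n) stop("k must not exceed the number of lines")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    te <- fold == f
    tr_design <- structure(list(X = design$X[!te, , drop = FALSE],
                                dosages = design$dosages[!te, , drop = FALSE],
                                y = design$y[!te], map = design$map),
                           class = "gp_design")
    fit <- fit_rrblup(tr_design)
    pred[te] <- predict_gebv(fit, design$X[te, , drop = FALSE],
                             design$dosages[te, , drop = FALSE])
    per_fold[f] <- suppressWarnings(stats::cor(design$y[te], pred[te]))
  }
  structure(list(fold = fold, predicted = pred,
                 accuracy = stats::cor(design$y, pred),
                 per_fold = per_fold, seed = seed),
            class = "cv_result")
}

#' Genome-ordered marker-effect profile
#'
#' Emits the fitted per-marker effects with their chromosome and position,
#' ordered genome-wide, for plotting (e.g. adjacent opposite-sign peaks at
#' linked QTL with opposing effects).
#'
#' @param fit an [fit_rrblup()] object whose design carried a marker map.
#' @param map optional data frame \code{snp, chrom, pos} overriding the map
#'   stored in the fit.
#' @return Data frame \code{snp, chrom, pos, effect} ordered by chromosome
#'   then position.
#' @export
marker_effect_profile <- function(fit, map = NULL) {
  stopifnot(inherits(fit, "rrblup_fit"))
  if (is.null(map)) map <- fit$map
  if (is.null(map)) stop("no marker map available")
  stopifnot(nrow(map) == length(fit$u))
  out <- cbind(map, effect = fit$u)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
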