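#' Fit the continuous severity function
#'
#' The severity index is a clipped weighted combination
#' \code{clip(w1 * brown + w2 * yellow, 0, 100)} mapping the feature vector
#' to \code{[0, 100]} (0 = no symptoms, 100 = substantial necrosis). The
#' weights are found by grid search over the ratio \code{w2/w1} in
#' \code{[0, 1]} (so \code{w1 >= w2 >= 0} always holds) with \code{w1} fixed
#' at 1; for every candidate the four score cutpoints partitioning
#' \code{[0, 100]} into five bands are chosen to minimise misclassification
#' of the ordinal labels when bands are read as scores. Cutpoint search is an
#' exact dynamic program over blocks of tied severity values, equivalent to
#' exhaustive search over midpoints of adjacent sorted values.
#'
#' @param data data frame with \code{yellow_pct}, \code{brown_pct},
#'   \code{label} (integers 1..5); at least two distinct labels.
#' @param grid_step resolution of the \code{w2/w1} grid (default 0.01).
#' @param w1 weight on brown\% (default 1; severity is clipped, not
#'   normalised, so the brown axis anchors 100).
#' @return A list of class \code{severity_model} with \code{w1}, \code{w2},
#'   \code{cutpoints} (4 strictly increasing values in (0, 100)) and
#'   \code{train_error} (misclassification rate of band-read scores).
#' @export
fit_severity <- function(data, grid_step = 0.01, w1 = 1) {
  stopifnot(all(c("yellow_pct", "brown_pct", "label") %in% names(data)))
  if (length(unique(data$label)) < 2) {
    stop("severity fitting needs at least two distinct labels")
  }
  bb <- data$brown_pct; yy <- data$yellow_pct
  lab <- as.integer(data$label)
  best <- list(err = Inf)
  for (w2 in seq(0, 1, by = grid_step)) {
    sev <- pmin(100, pmax(0, w1 * bb + w1 * w2 * yy))
    oc <- optimal_cutpoints(sev, lab)
    if (oc$err < best$err - 1e-12) {
      best <- list(err = oc$err, w2 = w1 * w2, cutpoints = oc$cutpoints)
    }
  }
  structure(list(w1 = w1, w2 = best$w2, cutpoints = best$cutpoints,
                 train_error = best$err),
            class = "severity_model")
}

#' Optimal ordinal cutpoints for a 1-D severity score
#'
#' Exact minimisation of misclassification when a scalar score is thresholded
#' into 5 ordered bands read as scores 1..5. Dynamic program over blocks of
#' tied score values (thresholding cannot separate ties); cutpoints fall at
#' midpoints between adjacent distinct values.
#'
#' @param sev numeric scores.
#' @param lab integer labels 1..5.
#' @return List with \code{cutpoints} (4 strictly increasing values) and
#'   \code{err} (minimal misclassification rate).
#' @export
optimal_cutpoints <- function(sev, lab) {
  stopifnot(length(sev) == length(lab), all(lab %in% 1:5))
  u <- sort(unique(sev))
  nb <- length(u)
  blk <- match(sev, u)
  cnt <- matrix(0, nb, 5)
  for (k in 1:5) {
    t <- tabulate(blk[lab == k], nbins = nb)
    cnt[, k] <- t
  }
  cum0 <- rbind(0, apply(cnt, 2, cumsum))  # rows j+1 <-> boundary after block j

  g_prev <- c(0, rep(-Inf, nb))
  back <- matrix(0L, nb + 1, 5)
  for (k in 1:5) {
    h <- g_prev - cum0[, k]
    hm <- cummax(h)
    j0 <- seq_along(h)
    arg <- cummax(ifelse(h == hm, j0, 0L))
    g_prev <- cum0[, k] + hm
    back[, k] <- arg
  }
  # backtrack boundaries after bands 1..4 (band 5 ends at the last block)
  bounds <- integer(4)
  j <- nb + 1
  for (k in 5:2) {
    j <- back[j, k]
    bounds[k - 1] <- j - 1  # block index 0..nb
  }
  cut_at <- function(j) {
    if (j <= 0) return(u[1] - 0.5)
    if (j >= nb) return(u[nb] + 0.5)
    (u[j] + u[j + 1]) / 2
  }
  cuts <- vapply(bounds, cut_at, numeric(1))
  cuts <- pmin(pmax(cuts, 1e-6), 100 - 1e-6)
  for (i in 2:4) if (cuts[i] <= cuts[i - 1]) cuts[i] <- cuts[i - 1] + 1e-6
  err <- 1 - (g_prev[nb + 1] / length(sev))
  list(cutpoints = cuts, err = err)
}

#' Continuous severity of a feature vector
#'
#' \code{clip(w1 * brown_pct + w2 * yellow_pct, 0, 100)}. Monotone
#' nondecreasing in both features since both weights are nonnegative.
#'
#' @param model a fitted [fit_severity()] model.
#' @param features data frame (or named vector) with \code{yellow_pct} and
#'   \code{brown_pct}.
#' @return Numeric severity values in \code{[0, 100]}.
#' @export
score_severity <- function(model, features) {
  stopifnot(inherits(model, "severity_model"))
  if (is.null(dim(features))) features <- as.data.frame(t(features))
  sev <- model$w1 * features$brown_pct + model$w2 * features$yellow_pct
  pmin(100, pmax(0, sev))
}

#' Read severity values as ordinal scores
#'
#' Thresholds severity values at the model's fitted cutpoints, giving the
#' score band (1..5) each value falls in.
#'
#' @param model a fitted [fit_severity()] model.
#' @param severity numeric severity values.
#' @return Integer scores 1..5.
#' @export
severity_to_score <- function(model, severity) {
  1L + findInterval(severity, model$cutpoints)
}
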