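#' Susceptibility grouping of IDC scores
#'
#' The first classification level works on three susceptibility groups:
#' LOW = scores {1,2}, MEDIUM = {3}, HIGH = {4,5}. MEDIUM has a single score,
#' so it routes directly to 3 with no second-level model.
#'
#' @param low,medium,high integer score sets; must partition 1..5.
#' @return Named list of class \code{susceptibility_groups}.
#' @export
susceptibility_groups <- function(low = c(1L, 2L), medium = 3L,
                                  high = c(4L, 5L)) {
  g <- list(LOW = as.integer(low), MEDIUM = as.integer(medium),
            HIGH = as.integer(high))
  if (!setequal(unlist(g), 1:5) || length(unlist(g)) != 5) {
    stop("groups must partition the scores 1..5")
  }
  structure(g, class = "susceptibility_groups")
}

#' Stratified train/test split
#'
#' Randomly splits a labeled feature set into training and testing subsets,
#' stratified by label so class proportions are preserved to within one row.
#' A class with fewer than 2 rows goes entirely to the training set with a
#' warning.
#'
#' @param data data frame with columns \code{yellow_pct}, \code{brown_pct}
#'   and integer \code{label} in 1..5.
#' @param train_frac fraction assigned to training, in (0, 1).
#' @param seed integer seed; the same seed reproduces the split.
#' @return List with data frames \code{train} and \code{test}.
#' @export
split_train_test <- function(data, train_frac = 0.75, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1,
            all(c("yellow_pct", "brown_pct", "label") %in% names(data)))
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in sort(unique(data$label))) {
    idx <- which(data$label == cl)
    if (length(idx) < 2) {
      warning("class ", cl, " has fewer than 2 rows; assigned entirely to train")
      train_idx <- c(train_idx, idx)
      next
    }
    n_tr <- round(train_frac * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  list(train = data[sort(train_idx), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
}

# standardize features with training statistics (zero-sd columns untouched)
.zfit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < .Machine$double.eps] <- 1
  list(mu = mu, sd = sd)
}
.zapply <- function(x, z) sweep(sweep(x, 2, z$mu), 2, z$sd, "/")

# binary linear SVM wrapper that degrades to a constant predictor when only
# one class is present; decision > 0 means "positive"
.fit_binary <- function(x, pos, cost) {
  if (all(pos) || all(!pos)) {
    return(list(constant = if (all(pos)) Inf else -Inf))
  }
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  list(svm = fit)
}

.decide_binary <- function(model, x) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
  pr <- stats::predict(model$svm, x, decision.values = TRUE)
  dvm <- attr(pr, "decision.values")
  dv <- drop(dvm)
  # e1071 orients the decision value toward whichever class came first in the
  # training data; the column name ("pos/neg" or "neg/pos") records it
  if (!startsWith(colnames(dvm)[1], "pos")) dv <- -dv
  dv
}

#' Train the hierarchical IDC classifier
#'
#' Two-level linear max-margin classifier over the (brown\%, yellow\%)
#' feature vector. Level 1 assigns a susceptibility group (LOW / MEDIUM /
#' HIGH) using pairwise (one-vs-one) linear SVMs with majority vote; vote
#' ties go to the lowest group index. Pairwise coupling is used because the
#' MEDIUM band lies between LOW and HIGH in feature space, so each pairwise
#' subproblem is linearly separable while a one-vs-rest middle-class margin
#' is not. Level 2 refines LOW into scores {1,2} and HIGH
#' into {4,5} with binary linear SVMs; MEDIUM routes deterministically to 3.
#' Features are z-scored with training statistics before fitting. A level-2
#' class absent from training degrades that branch to a constant predictor
#' with a warning.
#'
#' @param train data frame with \code{yellow_pct}, \code{brown_pct},
#'   \code{label} (integers 1..5); must be non-empty.
#' @param cost SVM regularisation constant (default 1).
#' @param groups a [susceptibility_groups()].
#' @return An object of class \code{idc_classifier}.
#' @export
train_hierarchical <- function(train, cost = 1, groups = susceptibility_groups()) {
  if (nrow(train) == 0) stop("empty training set")
  stopifnot(all(train$label %in% 1:5))
  x <- as.matrix(train[, c("yellow_pct", "brown_pct")])
  z <- .zfit(x)
  xs <- .zapply(x, z)
  grp_of <- function(lbl) {
    names(groups)[vapply(lbl, function(l)
      which(vapply(groups, function(g) l %in% g, logical(1))), integer(1))]
  }
  g <- grp_of(train$label)

  # pairwise linear SVMs between the groups present in training
  present <- names(groups)[names(groups) %in% unique(g)]
  pairs <- if (length(present) >= 2) utils::combn(present, 2, simplify = FALSE) else list()
  stage1 <- lapply(pairs, function(pr) {
    rows <- g %in% pr
    m <- .fit_binary(xs[rows, , drop = FALSE], g[rows] == pr[1], cost)
    m$pair <- pr
    m
  })

  fit_stage2 <- function(scores) {
    rows <- train$label %in% scores
    present <- sort(unique(train$label[rows]))
    if (length(present) == 0) {
      return(list(constant = min(scores)))
    }
    if (length(present) == 1) {
      warning("only score ", present, " present in group {",
              paste(scores, collapse = ","), "}; constant predictor used")
      return(list(constant = present))
    }
    m <- .fit_binary(xs[rows, , drop = FALSE], train$label[rows] == scores[1], cost)
    m$scores <- scores
    m
  }
  structure(list(
    stage1 = stage1, stage1_groups = present,
    stage2_low = fit_stage2(groups$LOW),
    stage2_high = fit_stage2(groups$HIGH),
    groups = groups, z = z, cost = cost
  ), class = "idc_classifier")
}

#' Predict IDC scores with the hierarchical classifier
#'
#' @param object a fitted [train_hierarchical()] model.
#' @param newdata data frame (or matrix) with columns \code{yellow_pct} and
#'   \code{brown_pct}.
#' @param ... unused.
#' @return Integer vector of scores in 1..5; the predicted score always lies
#'   in the predicted level-1 group.
#' @export
predict.idc_classifier <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, c("yellow_pct", "brown_pct")])
  xs <- .zapply(x, object$z)
  grp_names <- names(object$groups)
  votes <- matrix(0, nrow(xs), length(grp_names),
                  dimnames = list(NULL, grp_names))
  if (length(object$stage1) == 0) {
    # single group in training: all rows route there
    votes[, object$stage1_groups[1]] <- 1
  } else {
    for (m in object$stage1) {
      d <- .decide_binary(m, xs)
      win <- ifelse(d >= 0, m$pair[1], m$pair[2])
      for (nm in unique(win)) votes[win == nm, nm] <- votes[win == nm, nm] + 1
    }
  }
  grp <- max.col(votes, ties.method = "first")  # vote tie -> lowest group index
  grp_nm <- grp_names[grp]

  refine <- function(model, idx) {
    if (length(idx) == 0) return(integer(0))
    if (!is.null(model$constant) && is.null(model$scores)) {
      return(rep(as.integer(model$constant), length(idx)))
    }
    d <- .decide_binary(model, xs[idx, , drop = FALSE])
    ifelse(d >= 0, model$scores[1], model$scores[2])
  }
  out <- integer(nrow(xs))
  out[grp_nm == "MEDIUM"] <- object$groups$MEDIUM[1]
  out[grp_nm == "LOW"] <- refine(object$stage2_low, which(grp_nm == "LOW"))
  out[grp_nm == "HIGH"] <- refine(object$stage2_high, which(grp_nm == "HIGH"))
  as.integer(out)
}

#' Classification metrics from a 5 x 5 confusion matrix
#'
#' @param confusion square matrix, rows = true score, columns = predicted.
#' @return List with \code{overall_accuracy}, \code{per_class_accuracy}
#'   (recall per true class; \code{NA} for absent classes),
#'   \code{avg_per_class_accuracy} (mean over classes present),
#'   \code{sensitivity} and \code{specificity} (one-vs-rest), and
#'   \code{classes_present}.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  row_tot <- rowSums(confusion)
  col_tot <- colSums(confusion)
  per_class <- unname(ifelse(row_tot > 0, tp / row_tot, NA_real_))
  present <- row_tot > 0
  spec <- (total - row_tot - col_tot + tp) / (total - row_tot)
  list(
    overall_accuracy = sum(tp) / total,
    per_class_accuracy = per_class,
    avg_per_class_accuracy = mean(per_class[present]),
    sensitivity = per_class,
    specificity = unname(ifelse(total - row_tot > 0, spec, NA_real_)),
    classes_present = unname(which(present))
  )
}

#' Evaluate the classifier on a labeled test set
#'
#' Builds the 5 x 5 confusion matrix of true vs predicted scores and derives
#' overall accuracy, per-class accuracy, average per-class accuracy (over
#' classes present in the test set) and one-vs-rest sensitivity/specificity.
#'
#' @param model a fitted \code{idc_classifier}.
#' @param test non-empty labeled data frame as in [train_hierarchical()].
#' @return A list of class \code{classification_report}: the confusion matrix
#'   plus all metrics from [metrics_from_confusion()].
#' @export
evaluate_classifier <- function(model, test) {
  if (nrow(test) == 0) stop("empty test set")
  pred <- predict(model, test)
  cm <- table(factor(test$label, levels = 1:5), factor(pred, levels = 1:5))
  cm <- matrix(cm, 5, 5, dimnames = list(true = 1:5, predicted = 1:5))
  out <- metrics_from_confusion(cm)
  out$confusion <- cm
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat("IDC classification report\n")
  cat(sprintf("  overall accuracy:           %.1f%%\n", 100 * x$overall_accuracy))
  cat(sprintf("  average per-class accuracy: %.1f%%\n",
              100 * x$avg_per_class_accuracy))
  cat("  confusion (rows = true, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}
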