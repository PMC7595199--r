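# Bootstrap-aggregated CART classification trees with out-of-bag scoring.
#
# Trees are plain CART: axis-aligned binary splits chosen by Gini impurity
# decrease, grown to purity (min_leaf = 1) by default.  Bagging draws n
# samples with replacement per tree; by default every feature is considered
# at every split (plain bagging); `mtry` enables random-subspace splits.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

fit_cart <- function(X, y, K, min_leaf = 1, mtry = ncol(X)) {
  p <- ncol(X)
  importance <- numeric(p)
  build <- function(idx) {
    counts <- tabulate(y[idx], K)
    if (sum(counts > 0) == 1L || length(idx) < 2 * min_leaf)
      return(list(leaf = TRUE, counts = counts, pred = which.max(counts)))
    feats <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    node_imp <- gini_impurity(counts)
    n <- length(idx)
    best <- NULL; best_gain <- 1e-12
    for (j in feats) {
      xv <- X[idx, j]
      ord <- order(xv)
      xs <- xv[ord]; ys <- y[idx][ord]
      left <- integer(K)
      for (i in seq_len(n - 1)) {
        left[ys[i]] <- left[ys[i]] + 1L
        if (xs[i + 1] - xs[i] <= 0) next
        right <- counts - left
        w <- (i * gini_impurity(left) +
              (n - i) * gini_impurity(right)) / n
        gain <- node_imp - w
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best <- list(j = j, thr = (xs[i] + xs[i + 1]) / 2,
                       lidx = idx[ord[seq_len(i)]],
                       ridx = idx[ord[(i + 1):n]])
        }
      }
    }
    if (is.null(best))
      return(list(leaf = TRUE, counts = counts, pred = which.max(counts)))
    importance[best$j] <<- importance[best$j] + best_gain * n
    list(leaf = FALSE, feature = best$j, threshold = best$thr,
         left = build(best$lidx), right = build(best$ridx))
  }
  tree <- build(seq_along(y))
  list(tree = tree, importance = importance)
}

predict_cart <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  node$pred
}

#' Fit bootstrap-aggregated classification trees
#'
#' Each of `n_trees` trees is fit on a bootstrap resample (n draws with
#' replacement) of the labeled feature table, using CART splits by Gini
#' impurity, grown to purity (`min_leaf = 1`).  Out-of-bag (OOB)
#' predictions -- for each sample, the majority vote over the trees whose
#' bootstrap excluded it -- provide an internal estimate of generalization.
#' Vote ties are broken by class prevalence, then label order.  Fully
#' deterministic under a fixed seed.
#'
#' @param table Data frame with a factor column `label` and numeric
#'   predictor columns (an `id` column, if present, is ignored), or a
#'   numeric matrix if `label` is given separately.
#' @param n_trees Number of trees (default 200).
#' @param seed Integer RNG seed.
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param mtry Features considered per split; `NULL` (default) uses all
#'   (plain bagging); an integer < p gives random-subspace splits.
#' @param label Optional factor of labels when `table` has no `label`
#'   column.
#' @return A `bagged_trees` model: trees, in-bag masks, OOB votes and
#'   predictions (`NA` for samples never out of bag, listed in
#'   `no_oob`), `feature_importance` (mean impurity decrease), labels and
#'   metadata.
#' @export
fit_bagged_trees <- function(table, n_trees = 200, seed = 1, min_leaf = 1,
                             mtry = NULL, label = NULL) {
  if (is.null(label)) {
    if (!"label" %in% names(table)) abort_param("table must have a 'label' column")
    label <- table$label
    table <- table[, setdiff(names(table), c("label", "id")), drop = FALSE]
  }
  y <- droplevels(as.factor(label))
  X <- as.matrix(as.data.frame(table))
  if (!is.numeric(X)) abort_param("predictors must be numeric")
  n <- nrow(X)
  if (n < 4) abort_degenerate("need at least 4 samples")
  if (nlevels(y) < 2) abort_degenerate("need at least 2 classes")
  if (all(apply(X, 2, function(c) length(unique(c)) == 1)))
    abort_degenerate("all features constant; nothing to split on")
  K <- nlevels(y)
  yi <- as.integer(y)
  p <- ncol(X)
  mtry_eff <- if (is.null(mtry)) p else min(mtry, p)

  trees <- vector("list", n_trees)
  inbag <- matrix(FALSE, n, n_trees)
  importance <- numeric(p)
  votes <- matrix(0L, n, K)
  oob_count <- integer(n)

  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      inbag[unique(idx), t] <- TRUE
      fit <- fit_cart(X[idx, , drop = FALSE], yi[idx], K,
                      min_leaf = min_leaf, mtry = mtry_eff)
      importance <- importance + fit$importance / length(idx)
      tree <- fit$tree
      trees[[t]] <- tree
      oob <- which(!inbag[, t])
      for (i in oob) {
        k <- predict_cart(tree, X[i, ])
        votes[i, k] <- votes[i, k] + 1L
        oob_count[i] <- oob_count[i] + 1L
      }
    }
  })

  prevalence <- tabulate(yi, K)
  oob_pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (oob_count[i] == 0) next
    v <- votes[i, ]
    cand <- which(v == max(v))
    if (length(cand) > 1) {
      cand <- cand[order(-prevalence[cand], cand)]
    }
    oob_pred[i] <- cand[1]
  }

  structure(list(
    trees = trees, inbag = inbag, n_trees = n_trees, seed = seed,
    levels = levels(y), y = y,
    oob_votes = votes, oob_count = oob_count,
    oob_predictions = factor(levels(y)[oob_pred], levels = levels(y)),
    no_oob = which(oob_count == 0),
    feature_importance = stats::setNames(importance / n_trees, colnames(X)),
    min_leaf = min_leaf, mtry = mtry_eff,
    feature_names = colnames(X)),
    class = "bagged_trees")
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("bagged_trees: %d trees, %d samples, classes: %s\n",
              x$n_trees, length(x$y), paste(x$levels, collapse = ", ")))
  cat(sprintf("  OOB accuracy: %.3f%s\n", oob_accuracy(x),
              if (length(x$no_oob))
                sprintf(" (%d sample(s) never out of bag)", length(x$no_oob))
              else ""))
  invisible(x)
}

#' Predict classes for new data
#' @param object A `bagged_trees` model.
#' @param newdata Data frame or matrix with the model's predictor columns.
#' @param ... Unused.
#' @return Factor of majority-vote predictions.
#' @export
predict.bagged_trees <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  K <- length(object$levels)
  prev <- tabulate(as.integer(object$y), K)
  pred <- apply(X, 1, function(x) {
    v <- integer(K)
    for (tr in object$trees) {
      k <- predict_cart(tr, x)
      v[k] <- v[k] + 1L
    }
    cand <- which(v == max(v))
    if (length(cand) > 1) cand <- cand[order(-prev[cand], cand)]
    cand[1]
  })
  factor(object$levels[pred], levels = object$levels)
}

#' Out-of-bag accuracy
#' @param model A `bagged_trees` model.
#' @return Proportion of correct OOB predictions (samples with no OOB tree
#'   excluded).
#' @export
oob_accuracy <- function(model) {
  ok <- !is.na(model$oob_predictions)
  mean(model$oob_predictions[ok] == model$y[ok])
}

# ---- confusion matrices ----------------------------------------------------

#' Construct a confusion matrix
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @param positive Label of the positive class.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn, positive = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_param("confusion counts must be nonnegative integers")
  structure(as.list(counts) , positive = positive, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix (positive = %s): TP=%d FP=%d FN=%d TN=%d\n",
              attr(x, "positive"), x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Out-of-bag confusion matrix
#'
#' Binary models give a single matrix against the chosen positive class;
#' multiclass models give one one-vs-rest matrix per class.  Samples with
#' no out-of-bag tree are excluded and reported via the `excluded`
#' attribute.
#'
#' @param model A `bagged_trees` model.
#' @param positive Positive class for binary tasks (default: second level).
#' @return A `confusion_matrix`, or a named list of them (one per class).
#' @export
oob_confusion <- function(model, positive = NULL) {
  ok <- !is.na(model$oob_predictions)
  pred <- model$oob_predictions[ok]
  truth <- model$y[ok]
  lv <- model$levels
  one <- function(pos) {
    cm <- confusion_matrix(
      tp = sum(pred == pos & truth == pos),
      fp = sum(pred == pos & truth != pos),
      fn = sum(pred != pos & truth == pos),
      tn = sum(pred != pos & truth != pos),
      positive = pos)
    attr(cm, "excluded") <- which(!ok)
    cm
  }
  if (length(lv) == 2) {
    one(positive %||% lv[2])
  } else {
    out <- lapply(lv, one)
    names(out) <- lv
    out
  }
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SE = TP / (TP + FN)`,
#' `SP = TN / (TN + FP)`.  A zero denominator leaves the corresponding
#' metric `NA` (explicitly undefined, never coerced to 0).
#'
#' @param cm A [confusion_matrix()].
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(cm) {
  tot <- cm$tp + cm$tn + cm$fp + cm$fn
  if (tot == 0) abort_param("empty confusion matrix")
  list(
    accuracy = (cm$tp + cm$tn) / tot,
    sensitivity = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
    specificity = if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else NA_real_)
}

#' Majority-class chance accuracy
#'
#' The accuracy of the best constant (baseline) classifier: the relative
#' frequency of the most common label.
#'
#' @param labels Vector or factor of class labels (>= 1).
#' @return Proportion in (0, 1].
#' @export
chance_accuracy <- function(labels) {
  if (length(labels) == 0) abort_param("need at least one label")
  max(table(labels)) / length(labels)
}
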