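# Random-forest out-of-bag permutation feature importance and threshold
# selection.
#
# The importance score of feature j is the average over trees of the
# ABSOLUTE difference between a tree's OOB misclassification error and its
# OOB error after permuting feature j's values within that tree's OOB set:
#   VI(N_j) = (1/nb_trees) * sum_t | err(N_j)^(t) - err(N_oobj)^(t) |
# Forests are fitted one-vs-rest per class so each disease keeps its own
# importance profile; the selection aggregate is the max over classes.
#
# Forest fitting uses randomForest (library defaults); the per-tree
# permutation machinery is implemented here because the library's built-in
# importance is the signed, sd-normalized variant, not the absolute form.

# Vectorized single-tree predictor on a getTree() matrix (numeric
# predictors only): column 1/2 = daughters, 3 = split var, 4 = split
# point, 5 = status (-1 terminal), 6 = predicted class index.
predict_rf_tree <- function(tree, X) {
  node <- rep.int(1L, nrow(X))
  repeat {
    active <- which(tree[node, 5] != -1)
    if (length(active) == 0) break
    nd <- node[active]
    v <- tree[nd, 3]
    goleft <- X[cbind(active, v)] <= tree[nd, 4]
    node[active] <- ifelse(goleft, tree[nd, 1], tree[nd, 2])
  }
  tree[node, 6]
}

#' Out-of-bag permutation importance (per class)
#'
#' For each class a one-vs-rest forest of `nb_trees` bootstrap trees is
#' fitted; each tree's OOB rows are re-predicted with each feature
#' permuted within the OOB set, and the per-tree absolute OOB-error
#' differences are averaged.
#'
#' @param table Feature table (rows = recordings) containing the registry
#'   columns; no missing values (impute first).
#' @param labels Class labels, one per row (default `table$label`).
#' @param nb_trees Trees per forest (default 500).
#' @param seed Integer seed (forest bootstrap + permutations).
#' @return Object of class `importance_table`: `vi` is a classes x
#'   features matrix, plus `nb_trees`, `seed`.
#' @export
oob_importance <- function(table, labels = table$label, nb_trees = 500,
                           seed = 1) {
  feats <- intersect(feature_registry()$name, names(table))
  X <- as.matrix(table[feats])
  if (anyNA(X)) stop("feature table contains missing values; impute first")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (min(table(labels)) < 10) stop("need >= 10 rows per class")
  p <- ncol(X)
  m_big <- NULL
  vi <- matrix(0, nrow = length(classes), ncol = p,
               dimnames = list(classes, feats))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    set.seed(derive_seed(seed, "selection") + ci)
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c(cl, "rest"))
    rf <- randomForest::randomForest(
      x = as.data.frame(X), y = y, ntree = nb_trees,
      keep.inbag = TRUE, keep.forest = TRUE)
    acc <- numeric(p)
    for (t in seq_len(nb_trees)) {
      oob <- which(rf$inbag[, t] == 0)
      m <- length(oob)
      if (m < 2) next
      tree <- randomForest::getTree(rf, t, labelVar = FALSE)
      X_oob <- X[oob, , drop = FALSE]
      y_oob <- as.integer(y[oob])  # 1 = class, 2 = rest
      err_base <- mean(predict_rf_tree(tree, X_oob) != y_oob)
      # stack the p permuted copies and traverse once
      big <- X_oob[rep.int(seq_len(m), p), , drop = FALSE]
      perm_cols <- vapply(seq_len(p), function(j) sample.int(m), integer(m))
      for (j in seq_len(p)) {
        rowsj <- ((j - 1) * m + 1):(j * m)
        big[rowsj, j] <- X_oob[perm_cols[, j], j]
      }
      pred <- predict_rf_tree(tree, big)
      errs <- colMeans(matrix(pred != rep.int(y_oob, p), nrow = m))
      acc <- acc + abs(errs - err_base)
    }
    vi[ci, ] <- acc / nb_trees
  }
  structure(list(vi = vi, nb_trees = nb_trees, seed = seed,
                 classes = classes, features = feats),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("<importance_table> %d classes x %d features, %d trees\n",
              nrow(x$vi), ncol(x$vi), x$nb_trees))
  top <- sort(apply(x$vi, 2, max), decreasing = TRUE)[1:min(8, ncol(x$vi))]
  cat("top max-class VI:\n")
  print(round(top, 4))
  invisible(x)
}

#' Threshold selection of prominent features
#'
#' A feature is selected when its maximum over-class VI exceeds
#' `threshold`; the result is ordered by descending max-VI with ties
#' broken by registry order.
#'
#' @param importances An `importance_table`.
#' @param threshold Importance threshold (>= 0; default 0.02, the value
#'   at which classification precision peaked in the source workflow).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(importances, threshold = 0.02) {
  stopifnot(inherits(importances, "importance_table"), threshold >= 0)
  maxvi <- apply(importances$vi, 2, max)
  sel <- which(maxvi > threshold)
  if (length(sel) == 0) {
    stop(sprintf(
      "no feature exceeds importance threshold %g (max observed %.4f); lower the threshold",
      threshold, max(maxvi)))
  }
  reg_rank <- match(names(maxvi)[sel], feature_registry()$name)
  ord <- order(-maxvi[sel], reg_rank)
  names(maxvi)[sel][ord]
}

#' Write an importance table as CSV (classes x features)
#' @param importances An `importance_table`.
#' @param path Output path.
#' @export
write_importance_csv <- function(importances, path) {
  utils::write.csv(as.data.frame(importances$vi), path, row.names = TRUE)
  invisible(path)
}
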