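#' Fit a bootstrap regression-tree ensemble
#'
#' Random-forest regression of a response (here: the multifunctionality
#' index) on plot-level features (the four single ecosystem functions). Each
#' tree is grown on a bootstrap resample with variance-reduction (CART)
#' splits over `mtry` randomly chosen features; the in-bag counts are kept so
#' out-of-bag (OOB) indices are available for permutation importance.
#'
#' @param X `data.frame` or matrix of features (plots x features).
#' @param y Numeric response vector.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split (default `ceiling(p/3)`).
#' @param min_node Minimum terminal-node size (default 5).
#' @param max_nodes Optional cap on terminal nodes per tree (e.g. 2 for
#'   stumps); `NULL` grows trees to the `min_node` limit.
#' @param seed Integer seed; the ensemble is reproducible.
#' @return List of class `"mf_forest"`: the fitted \pkg{randomForest}
#'   object, the in-bag matrix, `X`, `y`, `oob_mse`, `oob_r2`, settings.
#' @export
fit_forest <- function(X, y, n_trees = 500, mtry = NULL, min_node = 5,
                       max_nodes = NULL, seed = 1L) {
  X <- as.data.frame(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, n_trees >= 1)
  if (stats::sd(y) == 0) stop("constant response: importance is undefined")
  if (is.null(mtry)) mtry <- ceiling(ncol(X) / 3)
  rf <- with_seed(seed, randomForest::randomForest(
    x = X, y = y, ntree = n_trees, mtry = mtry, nodesize = min_node,
    maxnodes = max_nodes, keep.inbag = TRUE, keep.forest = TRUE,
    importance = FALSE))
  obj <- list(rf = rf, inbag = rf$inbag, X = X, y = y,
              settings = list(n_trees = n_trees, mtry = mtry,
                              min_node = min_node, max_nodes = max_nodes,
                              seed = seed))
  base <- oob_predictions(obj, X)
  obj$oob_mse <- mean((y - base)^2, na.rm = TRUE)
  obj$oob_r2 <- 1 - obj$oob_mse / mean((y - mean(y))^2)
  class(obj) <- "mf_forest"
  obj
}

# per-observation mean of tree predictions restricted to trees where the
# observation was out of bag
oob_predictions <- function(forest, newX) {
  ind <- stats::predict(forest$rf, newdata = newX, predict.all = TRUE)$individual
  oob <- forest$inbag == 0
  pred <- rowSums(ind * oob) / rowSums(oob)
  pred[rowSums(oob) == 0] <- NA_real_
  pred
}

#' @export
predict.mf_forest <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  stats::predict(object$rf, newdata = newdata, ...)
}

#' Out-of-bag permutation importance and ranking
#'
#' Importance of a feature = mean increase in OOB mean-squared error when that
#' feature's column is randomly permuted (`n_perm` independent shuffles),
#' relative to the intact OOB MSE. Negative values are floored at 0. Ranks
#' are assigned by descending score with deterministic ties broken by feature
#' name order.
#'
#' When the response is itself an average of the features (as with the
#' multifunctionality index over the four single functions), the ranking
#' reflects each function's variance/covariance contribution to MF, not a
#' causal weight — a note to that effect is attached.
#'
#' @param forest A [fit_forest()] result.
#' @param n_perm Permutations per feature (default 10).
#' @param seed Integer seed for the shuffles.
#' @return `data.frame` of class `"mf_importance"`: `feature`, `importance`,
#'   `rank`, with the ensemble settings in `attr(, "settings")`.
#' @export
permutation_importance <- function(forest, n_perm = 10, seed = 1L) {
  stopifnot(inherits(forest, "mf_forest"), n_perm >= 1)
  X <- forest$X
  y <- forest$y
  base_mse <- forest$oob_mse
  scores <- with_seed(seed, {
    vapply(names(X), function(j) {
      mses <- vapply(seq_len(n_perm), function(k) {
        Xp <- X
        Xp[[j]] <- X[[j]][sample.int(nrow(X))]
        mean((y - oob_predictions(forest, Xp))^2, na.rm = TRUE)
      }, numeric(1))
      mean(mses) - base_mse
    }, numeric(1))
  })
  scores <- pmax(scores, 0)
  ord <- order(-scores, names(X))
  out <- data.frame(feature = names(X)[ord],
                    importance = unname(scores[ord]),
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  attr(out, "settings") <- c(forest$settings, list(n_perm = n_perm,
                                                   perm_seed = seed))
  class(out) <- c("mf_importance", class(out))
  out
}

#' @export
print.mf_importance <- function(x, ...) {
  cat("OOB permutation importance (descending):\n")
  print.data.frame(x, row.names = FALSE)
  cat("ordering:", paste(x$feature, collapse = " > "), "\n")
  invisible(x)
}

#' Rank the four single ecosystem functions by importance for MF
#'
#' Convenience wrapper: fits the forest of MF on the four standardized single
#' functions and returns the permutation-importance ranking.
#'
#' @param fm Output of [multifunctionality()] (function columns + `MF`).
#' @param n_trees,mtry,n_perm,seed Passed through.
#' @return An `"mf_importance"` table.
#' @export
rank_function_importance <- function(fm, n_trees = 500, mtry = NULL,
                                     n_perm = 10, seed = 1L) {
  cols <- mf_function_names()
  stopifnot(all(c(cols, "MF") %in% names(fm)))
  forest <- fit_forest(fm[, cols], fm$MF, n_trees = n_trees, mtry = mtry,
                       seed = seed)
  permutation_importance(forest, n_perm = n_perm, seed = seed + 1L)
}
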