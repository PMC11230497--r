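# R interface to the in-package gradient-boosted regression trees.

#' Fit a gradient-boosted regression-tree ensemble
#'
#' Stage-wise additive fitting of depth-limited regression trees to residuals
#' under squared-error loss (exact greedy split search, shrinkage by
#' `learning_rate`). Impurity decreases are accumulated per feature (the MDI
#' importance).
#'
#' @param X Numeric matrix or data frame of predictors (columns named).
#' @param y Numeric outcome.
#' @param n_trees Number of boosting stages; default 150.
#' @param max_depth Maximum tree depth; default 3.
#' @param min_node Minimum observations per child; default 10.
#' @param learning_rate Shrinkage; default 0.1.
#' @return An object of class `gbrt` with `init`, `trees`, `mdi` (named,
#'   raw impurity decreases), and the hyperparameters.
#' @export
gbrt_fit <- function(X, y, n_trees = 150, max_depth = 3, min_node = 10,
                     learning_rate = 0.1) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) {
    stop_brainclock("predictors and outcome must not contain missing values",
                    class = "brainclock_input_error")
  }
  if (var(y) == 0) {
    stop_brainclock("constant outcome: nothing to fit", class = "brainclock_input_error")
  }
  fit <- .gbrt_fit_cpp(X, y, as.integer(n_trees), as.integer(max_depth),
                       as.integer(min_node), learning_rate)
  names(fit$mdi) <- colnames(X)
  structure(
    list(init = fit$init, trees = fit$trees, mdi = fit$mdi,
         learning_rate = learning_rate, n_trees = n_trees,
         max_depth = max_depth, min_node = min_node,
         feature_names = colnames(X)),
    class = "gbrt"
  )
}

#' @export
predict.gbrt <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  as.numeric(.gbrt_predict_cpp(object$trees, object$init,
                               object$learning_rate, X))
}

#' @export
print.gbrt <- function(x, ...) {
  cat(sprintf("<gbrt> %d trees, depth <= %d, learning rate %g, %d features\n",
              x$n_trees, x$max_depth, x$learning_rate, length(x$feature_names)))
  invisible(x)
}
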