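# Two-layer graph convolutional age regressor.
#
# Propagation uses the renormalized adjacency Ahat = D^(-1/2) (A + I) D^(-1/2)
# where D is diagonal with the row sums of |A + I|: Omega edge weights can be
# negative, so degrees are taken on absolute values to keep Ahat well
# defined. Forward pass:
#
#   H1 = relu(Ahat %*% X %*% W1)        (dropout on H1 during training)
#   H2 = Ahat %*% H1 %*% W2             (no activation; W2 maps to 1 channel)
#   prediction = mean over nodes of H2, rescaled to years
#
# Training minimizes MSE with the Adam optimizer. Targets are standardized
# internally (train-side mean/sd) for optimizer stability; predictions are
# always reported in years. Hyperparameters (learning rate, epochs) are
# selected by grid search with age-stratified 5-fold cross-validation on the
# training side, then the model is retrained on the full training side.

#' Renormalized adjacency for signed weighted graphs
#'
#' `Ahat = D^(-1/2) (A + I) D^(-1/2)` with `D = diag(rowSums(abs(A + I)))`.
#' @param A Square (possibly signed) adjacency matrix.
#' @return Normalized adjacency of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A1 <- A + diag(nrow(A))
  d <- rowSums(abs(A1))
  d[d == 0] <- 1
  s <- 1 / sqrt(d)
  A1 * outer(s, s)
}

#' Initialize GCN parameters
#'
#' Glorot-uniform weight matrices `W1` (features x hidden) and `W2`
#' (hidden x 1); no bias terms.
#'
#' @param n_features Input feature dimension (= number of regions).
#' @param hidden_dim Hidden width; default 32.
#' @param dropout_rate Dropout probability on the first layer's output during
#'   training; default 0.5.
#' @param seed Integer seed for the initialization.
#' @return An object of class `gcn_params`.
#' @export
gcn_params <- function(n_features, hidden_dim = 32, dropout_rate = 0.5, seed = 1L) {
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  with_seed(seed, {
    structure(
      list(W1 = glorot(n_features, hidden_dim),
           W2 = glorot(hidden_dim, 1L),
           hidden_dim = as.integer(hidden_dim),
           dropout_rate = dropout_rate,
           y_center = 0, y_scale = 1),
      class = "gcn_params"
    )
  })
}

#' GCN forward pass for one graph
#'
#' Deterministic when `training = FALSE` (dropout disabled). Output is in
#' years (after the parameters' internal target rescaling; freshly
#' initialized parameters have identity scaling).
#'
#' @param graph A `brain_graph`.
#' @param params A `gcn_params` (or the `params` of a trained model).
#' @param training Apply dropout?
#' @return Predicted age, scalar.
#' @export
gcn_forward <- function(graph, params, training = FALSE) {
  X <- graph$node_features
  if (ncol(X) != nrow(params$W1)) {
    stop_brainclock("feature dimension %d does not match W1 (%d rows)",
                    ncol(X), nrow(params$W1), class = "brainclock_input_error")
  }
  Ahat <- normalize_adjacency(graph$adjacency)
  H1 <- pmax(Ahat %*% X %*% params$W1, 0)
  if (training && params$dropout_rate > 0) {
    keep <- matrix(rbinom(length(H1), 1L, 1 - params$dropout_rate), nrow(H1))
    H1 <- H1 * keep / (1 - params$dropout_rate)
  }
  H2 <- Ahat %*% H1 %*% params$W2
  mean(H2) * params$y_scale + params$y_center
}

# Precompute the training-time sufficient statistics of a graph:
# P = Ahat %*% X and u = colSums(Ahat)/N (mean pooling absorbed into u,
# since mean(Ahat H W2) = (u' H) W2).
prepare_graph <- function(g) {
  Ahat <- normalize_adjacency(g$adjacency)
  list(P = Ahat %*% g$node_features,
       u = colSums(Ahat) / nrow(Ahat),
       y = g$target_age)
}

# Core Adam training loop on prepared graphs; targets standardized by
# (y_center, y_scale). Returns updated weights and per-epoch training MSE
# (in years^2).
train_gcn_core <- function(prep, W1, W2, lr, epochs, batch_size, dropout,
                           y_center, y_scale, seed) {
  n <- length(prep)
  mW1 <- vW1 <- matrix(0, nrow(W1), ncol(W1))
  mW2 <- vW2 <- matrix(0, nrow(W2), ncol(W2))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  log_mse <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      sse <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        gW1 <- matrix(0, nrow(W1), ncol(W1))
        gW2 <- matrix(0, nrow(W2), ncol(W2))
        for (k in idx) {
          p <- prep[[k]]
          H1 <- pmax(p$P %*% W1, 0)
          act <- H1 > 0
          if (dropout > 0) {
            keep <- matrix(rbinom(length(H1), 1L, 1 - dropout), nrow(H1))
            H1d <- H1 * keep / (1 - dropout)
          } else {
            H1d <- H1
          }
          pred <- drop(crossprod(p$u, H1d) %*% W2)
          y_std <- (p$y - y_center) / y_scale
          e <- pred - y_std
          sse <- sse + (e * y_scale)^2
          g_out <- 2 * e / length(idx)
          gW2 <- gW2 + g_out * crossprod(H1d, p$u)
          dH1 <- g_out * outer(p$u, drop(W2))
          if (dropout > 0) dH1 <- dH1 * keep / (1 - dropout)
          dH1 <- dH1 * act
          gW1 <- gW1 + crossprod(p$P, dH1)
        }
        step <- step + 1L
        # Adam updates
        mW1 <- b1 * mW1 + (1 - b1) * gW1; vW1 <- b2 * vW1 + (1 - b2) * gW1^2
        mW2 <- b1 * mW2 + (1 - b1) * gW2; vW2 <- b2 * vW2 + (1 - b2) * gW2^2
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        W1 <- W1 - lr * (mW1 / c1) / (sqrt(vW1 / c2) + eps)
        W2 <- W2 - lr * (mW2 / c1) / (sqrt(vW2 / c2) + eps)
        if (!all(is.finite(W1)) || !all(is.finite(W2))) {
          return(list(W1 = W1, W2 = W2, log_mse = log_mse, diverged = TRUE))
        }
      }
      log_mse[ep] <- sse / n
    }
    list(W1 = W1, W2 = W2, log_mse = log_mse, diverged = FALSE)
  })
}

eval_mse_years <- function(prep, W1, W2, y_center, y_scale) {
  errs <- vapply(prep, function(p) {
    H1 <- pmax(p$P %*% W1, 0)
    pred <- drop(crossprod(p$u, H1) %*% W2) * y_scale + y_center
    (pred - p$y)^2
  }, numeric(1))
  mean(errs)
}

#' Training plan for the GCN grid search
#'
#' @param learning_rate_grid Learning rates to try.
#' @param epoch_grid Epoch counts to try.
#' @param k_folds Inner cross-validation folds (5, per protocol).
#' @param batch_size Minibatch size.
#' @param hidden_dim Hidden width of the first convolution.
#' @param dropout_rate Dropout probability during training.
#' @param n_age_bins Age bins used to stratify the CV folds.
#' @param seed Integer seed controlling weight init, fold assignment, dropout
#'   masks, and batch order.
#' @return An object of class `training_plan`.
#' @export
training_plan <- function(learning_rate_grid = c(1e-2, 1e-3, 1e-4),
                          epoch_grid = c(50, 100, 200),
                          k_folds = 5,
                          batch_size = 16,
                          hidden_dim = 32,
                          dropout_rate = 0.5,
                          n_age_bins = 5,
                          seed = 1L) {
  if (!length(learning_rate_grid) || !length(epoch_grid)) {
    stop_brainclock("hyperparameter grids must be non-empty",
                    class = "brainclock_config_error")
  }
  structure(
    list(learning_rate_grid = learning_rate_grid, epoch_grid = epoch_grid,
         k_folds = as.integer(k_folds), batch_size = as.integer(batch_size),
         hidden_dim = as.integer(hidden_dim), dropout_rate = dropout_rate,
         n_age_bins = as.integer(n_age_bins), seed = as.integer(seed)),
    class = "training_plan"
  )
}

#' Train the GCN with grid search and inner cross-validation
#'
#' For every (learning rate, epochs) combination, runs k-fold cross-validation
#' on the training side with folds stratified by age bin; augmented graphs
#' always join the fit portion of every fold and are never used for
#' validation. The combination minimizing mean validation MSE (ties: first in
#' grid order) is retrained on the full training side. Combinations with
#' non-finite losses are marked failed and excluded.
#'
#' @param split A [stratified_split()] result whose `train` side may include
#'   [augment_by_interpolation()] graphs.
#' @param plan A [training_plan()].
#' @return An object of class `trained_gcn`: `params`, `best_hyperparams`,
#'   `cv_table` (one row per combination: mean/sd validation MSE in years^2),
#'   `training_log` (final-fit per-epoch MSE), `region_labels`, `modality`.
#' @export
train_with_grid_search <- function(split, plan = training_plan()) {
  stopifnot(inherits(split, "dataset_split"), inherits(plan, "training_plan"))
  train <- split$train
  if (!length(train)) {
    stop_brainclock("empty training set", class = "brainclock_input_error")
  }
  modality <- unique(vapply(train, function(g) g$modality %||% "fMRI", character(1)))
  if (length(modality) != 1) {
    stop_brainclock("mixed modalities in one training set: %s",
                    paste(modality, collapse = ", "),
                    class = "brainclock_input_error")
  }
  is_aug <- vapply(train, function(g) isTRUE(g$is_augmented), logical(1))
  real <- train[!is_aug]
  aug <- train[is_aug]
  if (!length(real)) {
    stop_brainclock("training set has no original (non-augmented) graphs",
                    class = "brainclock_input_error")
  }
  ages <- vapply(real, function(g) g$target_age, numeric(1))
  y_center <- mean(ages)
  y_scale <- if (sd(ages) > 0) sd(ages) else 1
  prep_real <- lapply(real, prepare_graph)
  prep_aug <- lapply(aug, prepare_graph)

  # age-stratified fold assignment over the real graphs
  k <- min(plan$k_folds, length(real))
  edges <- seq(min(ages), max(ages), length.out = plan$n_age_bins + 1L)
  bin <- findInterval(ages, edges, rightmost.closed = TRUE, all.inside = TRUE)
  fold <- integer(length(real))
  with_seed(child_seed(plan$seed, 1L), {
    for (b in unique(bin)) {
      members <- which(bin == b)
      members <- if (length(members) == 1L) members else sample(members)
      fold[members] <- rep_len(seq_len(k), length(members))
    }
  })

  grid <- expand.grid(epochs = plan$epoch_grid, lr = plan$learning_rate_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("lr", "epochs")]
  n_feat <- ncol(real[[1]]$node_features)
  cv_mean <- cv_sd <- rep(NA_real_, nrow(grid))
  failed <- logical(nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    fold_mse <- rep(NA_real_, k)
    diverged <- FALSE
    for (f in seq_len(k)) {
      fit_prep <- c(prep_real[fold != f], prep_aug)
      val_prep <- prep_real[fold == f]
      if (!length(val_prep)) next
      init <- gcn_params(n_feat, plan$hidden_dim, plan$dropout_rate,
                         seed = child_seed(plan$seed, 100L + ci))
      res <- train_gcn_core(fit_prep, init$W1, init$W2, grid$lr[ci],
                            grid$epochs[ci], plan$batch_size,
                            plan$dropout_rate, y_center, y_scale,
                            seed = child_seed(plan$seed, 1000L * ci + f))
      if (res$diverged) {
        diverged <- TRUE
        break
      }
      fold_mse[f] <- eval_mse_years(val_prep, res$W1, res$W2, y_center, y_scale)
    }
    ok <- fold_mse[is.finite(fold_mse)]
    if (diverged || !length(ok)) {
      failed[ci] <- TRUE
    } else {
      cv_mean[ci] <- mean(ok)
      cv_sd[ci] <- if (length(ok) > 1) sd(ok) else 0
    }
  }
  cv_table <- data.frame(lr = grid$lr, epochs = grid$epochs,
                         mean_val_mse = cv_mean, sd_val_mse = cv_sd,
                         failed = failed)
  if (all(failed | !is.finite(cv_mean))) {
    stop_brainclock("all hyperparameter combinations failed (non-finite loss)",
                    class = "brainclock_training_error")
  }
  best_idx <- which(!failed & is.finite(cv_mean))
  best_idx <- best_idx[which.min(cv_mean[best_idx])]
  best <- list(lr = grid$lr[best_idx], epochs = grid$epochs[best_idx])

  init <- gcn_params(n_feat, plan$hidden_dim, plan$dropout_rate,
                     seed = child_seed(plan$seed, 7L))
  final <- train_gcn_core(c(prep_real, prep_aug), init$W1, init$W2, best$lr,
                          best$epochs, plan$batch_size, plan$dropout_rate,
                          y_center, y_scale, seed = child_seed(plan$seed, 9L))
  params <- init
  params$W1 <- final$W1
  params$W2 <- final$W2
  params$y_center <- y_center
  params$y_scale <- y_scale
  structure(
    list(params = params, best_hyperparams = best, cv_table = cv_table,
         training_log = final$log_mse,
         region_labels = real[[1]]$region_labels,
         modality = modality, plan = plan),
    class = "trained_gcn"
  )
}

#' @export
print.trained_gcn <- function(x, ...) {
  cat(sprintf("<trained_gcn> %s, %d-dim features, hidden %d\n", x$modality,
              nrow(x$params$W1), x$params$hidden_dim))
  cat(sprintf("  best: lr=%g epochs=%d (CV MSE %.2f years^2)\n",
              x$best_hyperparams$lr, x$best_hyperparams$epochs,
              min(x$cv_table$mean_val_mse, na.rm = TRUE)))
  invisible(x)
}

#' Predict ages for a list of graphs
#'
#' Deterministic inference (dropout off). Refuses graphs whose region label
#' order differs from the model's.
#'
#' @param graphs List of `brain_graph` objects.
#' @param model A `trained_gcn`.
#' @return Data frame with `subject_id`, `y` (chronological age), `y_hat`.
#' @export
predict_batch <- function(graphs, model) {
  stopifnot(inherits(model, "trained_gcn"))
  if (!length(graphs)) {
    return(data.frame(subject_id = character(0), y = numeric(0),
                      y_hat = numeric(0)))
  }
  preds <- vapply(graphs, function(g) {
    if (!is.null(g$region_labels) &&
        !identical(g$region_labels, model$region_labels)) {
      stop_brainclock("region label order of graph '%s' does not match the model",
                      g$subject_id, class = "brainclock_input_error")
    }
    if (!is.null(g$modality) && g$modality != model$modality) {
      stop_brainclock("graph '%s' is %s but the model was trained on %s",
                      g$subject_id, g$modality, model$modality,
                      class = "brainclock_input_error")
    }
    gcn_forward(g, model$params, training = FALSE)
  }, numeric(1))
  data.frame(
    subject_id = vapply(graphs, function(g) g$subject_id, character(1)),
    y = vapply(graphs, function(g) g$target_age, numeric(1)),
    y_hat = preds,
    stringsAsFactors = FALSE
  )
}

#' Save / load a trained model checkpoint (JSON)
#'
#' The checkpoint holds the weight matrices, hyperparameters, grid table,
#' seed, and the region-label order the model expects.
#' @param model A `trained_gcn`.
#' @param path Output path.
#' @return `path` invisibly; `load_gcn_model()` returns the model.
#' @export
save_gcn_model <- function(model, path) {
  stopifnot(inherits(model, "trained_gcn"))
  obj <- list(
    W1 = model$params$W1, W2 = model$params$W2,
    hidden_dim = model$params$hidden_dim,
    dropout_rate = model$params$dropout_rate,
    y_center = model$params$y_center, y_scale = model$params$y_scale,
    best_hyperparams = model$best_hyperparams,
    cv_table = model$cv_table,
    region_labels = model$region_labels,
    modality = model$modality,
    seed = model$plan$seed
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_gcn_model
#' @export
load_gcn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- structure(
    list(W1 = obj$W1, W2 = matrix(obj$W2, ncol = 1),
         hidden_dim = obj$hidden_dim, dropout_rate = obj$dropout_rate,
         y_center = obj$y_center, y_scale = obj$y_scale),
    class = "gcn_params"
  )
  structure(
    list(params = params, best_hyperparams = obj$best_hyperparams,
         cv_table = obj$cv_table, training_log = NULL,
         region_labels = obj$region_labels, modality = obj$modality,
         plan = list(seed = obj$seed)),
    class = "trained_gcn"
  )
}
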