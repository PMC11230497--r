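# Gradient-boosting regressions of BAG on country-level exposome and
# disparity indicators, with repeated cross-validation and multi-method
# feature importance (permutation + MDI; both are required methods — an
# external SHAP adapter can be plugged in but is not part of the contract).

EXPOSOME_PREDICTORS <- c("gini", "pm25", "comm_burden", "noncomm_burden",
                         "gii", "diagnosis_any", "sex_f", "region_lac")

#' Build a subject-level exposome design
#'
#' Joins country-level indicators onto subjects through the cohort's
#' `country` column (an ecological design: country values are broadcast to
#' subjects, which ignores within-country clustering — a warning notes this)
#' and encodes the subject-level flags: `diagnosis_any` (1 for MCI/AD/bvFTD
#' versus 0 for HC), `sex_f`, `region_lac`.
#'
#' @param cohort A cohort table with `country`, `diagnosis`, `sex`, `region`.
#' @param exposome A [generate_exposome_table()]-shaped country table.
#' @param bag Numeric BAG outcome, one per cohort row.
#' @param predictors Character subset of `gini`, `pm25`, `comm_burden`,
#'   `noncomm_burden`, `gii`, `diagnosis_any`, `sex_f`, `region_lac`.
#' @return An object of class `exposome_design`: `X` (numeric predictor
#'   matrix), `bag`, `predictors`.
#' @export
exposome_design <- function(cohort, exposome, bag,
                            predictors = c("gini", "pm25", "comm_burden",
                                           "noncomm_burden", "diagnosis_any")) {
  predictors <- match.arg(predictors, EXPOSOME_PREDICTORS, several.ok = TRUE)
  idx <- match(cohort$country, exposome$country)
  if (anyNA(idx)) {
    stop_brainclock("exposome table is missing countries: %s",
                    paste(unique(cohort$country[is.na(idx)]), collapse = ", "),
                    class = "brainclock_input_error")
  }
  if (length(bag) != nrow(cohort) || anyNA(bag)) {
    stop_brainclock("bag must be complete and match the cohort rows",
                    class = "brainclock_input_error")
  }
  full <- data.frame(
    gini = exposome$gini[idx],
    pm25 = exposome$pm25[idx],
    comm_burden = exposome$comm_burden[idx],
    noncomm_burden = exposome$noncomm_burden[idx],
    gii = exposome$gii[idx],
    diagnosis_any = as.numeric(cohort$diagnosis != "HC"),
    sex_f = as.numeric(cohort$sex == "F"),
    region_lac = as.numeric(cohort$region == "LAC")
  )
  X <- as.matrix(full[, predictors, drop = FALSE])
  if (anyNA(X)) {
    stop_brainclock("missing values after the exposome join",
                    class = "brainclock_input_error")
  }
  warning("country-level predictors are broadcast to subjects; ",
          "within-country clustering is ignored (ecological design)",
          call. = FALSE)
  structure(list(X = X, bag = as.numeric(bag), predictors = predictors),
            class = "exposome_design")
}

default_gbrt_grid <- function() {
  expand.grid(n_trees = c(100, 300), max_depth = c(2, 3),
              learning_rate = c(0.05, 0.1), KEEP.OUT.ATTRS = FALSE)
}

fold_ids <- function(n, k, seed) {
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Gradient-boosting regression of BAG with repeated cross-validation
#'
#' Hyperparameters (number of trees, depth, learning rate) are selected from
#' a small exhaustive grid by 10-fold cross-validated RMSE. With the selected
#' combination, k-fold cross-validation is repeated `n_repeats` times; each
#' held-out fold (10% of the data per fold) contributes one row of R-squared,
#' Cohen's f2, and RMSE to the metrics table (`n_folds * n_repeats` rows).
#' The final ensemble is refit on all data.
#'
#' @param design An [exposome_design()].
#' @param n_folds CV folds (default 10, each fold 10% held out).
#' @param n_repeats CV repetitions (default 10).
#' @param seed Integer seed.
#' @param grid Data frame of candidate `n_trees`, `max_depth`,
#'   `learning_rate` rows.
#' @return An object of class `bag_regression`: `model` (a [gbrt_fit()]
#'   ensemble on all data), `best` hyperparameters, `metrics` (per
#'   repeat x fold), `cv_r2` / `cv_f2` / `cv_rmse` means.
#' @export
fit_bag_regression <- function(design, n_folds = 10, n_repeats = 10,
                               seed = 1L, grid = default_gbrt_grid()) {
  stopifnot(inherits(design, "exposome_design"))
  X <- design$X
  y <- design$bag
  n <- nrow(X)
  if (n < 10 * n_folds) {
    stop_brainclock("need at least %d rows for %d-fold repeated CV, got %d",
                    10L * n_folds, n_folds, n, class = "brainclock_input_error")
  }
  if (var(y) == 0) {
    stop_brainclock("constant outcome", class = "brainclock_input_error")
  }
  # grid selection on one seeded 10-fold pass, scored by CV RMSE
  sel_fold <- fold_ids(n, n_folds, child_seed(seed, 1L))
  grid_rmse <- vapply(seq_len(nrow(grid)), function(gi) {
    sq <- 0
    for (f in seq_len(n_folds)) {
      tr <- sel_fold != f
      fit <- gbrt_fit(X[tr, , drop = FALSE], y[tr],
                      n_trees = grid$n_trees[gi],
                      max_depth = grid$max_depth[gi],
                      learning_rate = grid$learning_rate[gi])
      sq <- sq + sum((y[!tr] - predict(fit, X[!tr, , drop = FALSE]))^2)
    }
    sqrt(sq / n)
  }, numeric(1))
  best <- as.list(grid[which.min(grid_rmse), ])

  metrics <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    fold <- fold_ids(n, n_folds, child_seed(seed, 100L + r))
    do.call(rbind, lapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      fit <- gbrt_fit(X[tr, , drop = FALSE], y[tr],
                      n_trees = best$n_trees, max_depth = best$max_depth,
                      learning_rate = best$learning_rate)
      pred <- predict(fit, X[!tr, , drop = FALSE])
      yt <- y[!tr]
      r2 <- 1 - sum((yt - pred)^2) / sum((yt - mean(yt))^2)
      data.frame(repeat_id = r, fold = f, r2 = r2, f2 = cohens_f2(r2),
                 rmse = sqrt(mean((yt - pred)^2)))
    }))
  }))
  model <- gbrt_fit(X, y, n_trees = best$n_trees, max_depth = best$max_depth,
                    learning_rate = best$learning_rate)
  structure(
    list(model = model, best = best, metrics = metrics,
         cv_r2 = mean(metrics$r2), cv_f2 = mean(metrics$f2),
         cv_rmse = mean(metrics$rmse), design = design,
         n_folds = n_folds, n_repeats = n_repeats, seed = as.integer(seed)),
    class = "bag_regression"
  )
}

#' @export
print.bag_regression <- function(x, ...) {
  cat(sprintf(
    "<bag_regression> %d x %d CV: R2=%.3f f2=%.3f RMSE=%.2f (trees=%d depth=%d lr=%g)\n",
    x$n_repeats, x$n_folds, x$cv_r2, x$cv_f2, x$cv_rmse,
    x$best$n_trees, x$best$max_depth, x$best$learning_rate))
  invisible(x)
}

#' Multi-method feature importance with confidence intervals
#'
#' Two required methods, mirroring the multi-method protocol:
#' \describe{
#'   \item{permutation}{Mean drop in held-out R-squared when one predictor
#'     column is shuffled, over `n_perm_repeats` independent shuffles on a
#'     seeded 90/10 hold-out split; the CI is the percentile interval of the
#'     repeated drops.}
#'   \item{MDI}{Normalized mean-decrease-in-impurity share per predictor,
#'     refit on `n_mdi_refits` bootstrap resamples of the design; percentile
#'     CI over refits.}
#' }
#' A predictor is significant under a method iff the lower CI bound is
#' strictly above zero (an interval crossing zero is non-significant); the
#' overall `significant` flag requires significance under both methods.
#'
#' @param fit A [fit_bag_regression()] result.
#' @param n_perm_repeats Shuffle repeats for permutation importance.
#' @param n_mdi_refits Bootstrap refits for the MDI interval.
#' @param ci Confidence level; default 0.99.
#' @param seed Integer seed.
#' @return An object of class `importance_summary`: data frame with one row
#'   per predictor x method (`mean`, `ci_low`, `ci_high`, `significant`) plus
#'   an `overall` attribute (per-predictor combined flag) and the fit's CV
#'   metrics.
#' @export
multi_method_importance <- function(fit, n_perm_repeats = 100,
                                    n_mdi_refits = 50, ci = 0.99, seed = 1L) {
  stopifnot(inherits(fit, "bag_regression"))
  X <- fit$design$X
  y <- fit$design$bag
  n <- nrow(X)
  p <- ncol(X)
  alpha <- (1 - ci) / 2
  best <- fit$best

  # permutation importance on a seeded 90/10 hold-out
  with_seed(child_seed(seed, 1L), {
    test_idx <- sample.int(n, max(2L, round(0.1 * n)))
  })
  tr <- setdiff(seq_len(n), test_idx)
  m <- gbrt_fit(X[tr, , drop = FALSE], y[tr], n_trees = best$n_trees,
                max_depth = best$max_depth, learning_rate = best$learning_rate)
  Xt <- X[test_idx, , drop = FALSE]
  yt <- y[test_idx]
  ss_tot <- sum((yt - mean(yt))^2)
  r2_base <- 1 - sum((yt - predict(m, Xt))^2) / ss_tot
  perm_drop <- matrix(0, n_perm_repeats, p, dimnames = list(NULL, colnames(X)))
  with_seed(child_seed(seed, 2L), {
    for (j in seq_len(p)) {
      for (r in seq_len(n_perm_repeats)) {
        Xs <- Xt
        Xs[, j] <- Xs[sample.int(nrow(Xs)), j]
        perm_drop[r, j] <- r2_base -
          (1 - sum((yt - predict(m, Xs))^2) / ss_tot)
      }
    }
  })

  # MDI share over bootstrap refits
  mdi_share <- matrix(0, n_mdi_refits, p, dimnames = list(NULL, colnames(X)))
  with_seed(child_seed(seed, 3L), {
    for (b in seq_len(n_mdi_refits)) {
      idx <- sample.int(n, replace = TRUE)
      mb <- gbrt_fit(X[idx, , drop = FALSE], y[idx], n_trees = best$n_trees,
                     max_depth = best$max_depth,
                     learning_rate = best$learning_rate)
      tot <- sum(mb$mdi)
      mdi_share[b, ] <- if (tot > 0) mb$mdi / tot else 0
    }
  })

  summarize <- function(mat, method) {
    data.frame(
      predictor = colnames(mat),
      method = method,
      mean = colMeans(mat),
      ci_low = apply(mat, 2, quantile, probs = alpha),
      ci_high = apply(mat, 2, quantile, probs = 1 - alpha),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(summarize(perm_drop, "permutation"), summarize(mdi_share, "mdi"))
  out$significant <- out$ci_low > 0
  rownames(out) <- NULL
  overall <- vapply(colnames(X), function(pr) {
    all(out$significant[out$predictor == pr])
  }, logical(1))
  attr(out, "overall") <- overall
  attr(out, "cv_r2") <- fit$cv_r2
  attr(out, "cv_f2") <- fit$cv_f2
  attr(out, "ci") <- ci
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("importance_summary", "data.frame")
  out
}
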