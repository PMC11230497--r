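# Fit metrics, brain-age gaps, subsample permutation tests, covariate
# adjustment, and within-scanner harmonization.

#' Brain-age gap per subject
#'
#' `bag = y_hat - y` (predicted minus chronological age, years); positive
#' values mean an older-looking brain.
#'
#' @param preds Data frame with columns `y` and `y_hat` (e.g. from
#'   [predict_batch()]).
#' @return The data frame with a `bag` column added/overwritten.
#' @export
compute_bag <- function(preds) {
  stopifnot(is.data.frame(preds), all(c("y", "y_hat") %in% names(preds)))
  preds$bag <- preds$y_hat - preds$y
  preds
}

#' Mean directional error
#'
#' Mean over subjects of `sign(y_hat - y)`: +1 when the model overpredicts a
#' subject's age, -1 when it underpredicts, 0 on exact ties. Values near zero
#' indicate balanced over/underestimation; the sign of MDE is a systematic
#' bias indicator.
#'
#' @param preds Data frame with `y`, `y_hat` — or a numeric vector `y` when
#'   `y_hat` is supplied separately.
#' @param y_hat Optional numeric vector of predictions.
#' @return MDE in `[-1, 1]`.
#' @export
compute_mde <- function(preds, y_hat = NULL) {
  if (is.data.frame(preds)) {
    y <- preds$y
    y_hat <- preds$y_hat
  } else {
    y <- preds
  }
  stopifnot(length(y) >= 1, length(y) == length(y_hat))
  mean(sign(y_hat - y))
}

#' Fit metrics for an age-prediction set
#'
#' RMSE (`sqrt(mean((y - y_hat)^2))`, years), R-squared
#' (`1 - SS_res/SS_tot`), Pearson correlation, Cohen's effect size
#' `f2 = R2/(1 - R2)` (capped at 1e6 as R2 -> 1), and the mean directional
#' error.
#'
#' @param preds Data frame with `y`, `y_hat`; needs `n >= 2` and variance in
#'   `y`.
#' @return An object of class `fit_metrics` (also a list): `rmse`, `r2`,
#'   `pearson_r`, `cohens_f2`, `mde`, `n`.
#' @export
compute_fit_metrics <- function(preds) {
  stopifnot(is.data.frame(preds), all(c("y", "y_hat") %in% names(preds)))
  y <- preds$y
  y_hat <- preds$y_hat
  n <- length(y)
  if (n < 2) {
    stop_brainclock("need at least 2 predictions", class = "brainclock_input_error")
  }
  if (var(y) == 0) {
    stop_brainclock("zero variance in chronological age: R-squared undefined",
                    class = "brainclock_input_error")
  }
  r2 <- 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  structure(
    list(rmse = sqrt(mean((y - y_hat)^2)),
         r2 = r2,
         pearson_r = cor(y, y_hat),
         cohens_f2 = cohens_f2(r2),
         mde = compute_mde(preds),
         n = n),
    class = "fit_metrics"
  )
}

#' Cohen's f-squared from R-squared
#'
#' `f2 = R2 / (1 - R2)`, capped at 1e6 to stay finite as `R2 -> 1`.
#' @param r2 R-squared value(s).
#' @return f-squared, same length.
#' @export
cohens_f2 <- function(r2) {
  pmin(r2 / pmax(1 - r2, 1e-12), 1e6)
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(
    "<fit_metrics> n=%d  RMSE=%.2f  R2=%.3f  r=%.3f  f2=%.3f  MDE=%.3f\n",
    x$n, x$rmse, x$r2, x$pearson_r, x$cohens_f2, x$mde))
  invisible(x)
}

#' Two-sided subsample permutation test for a group difference in BAG
#'
#' The observed statistic is `mean(bag_a) - mean(bag_b)` on the full groups.
#' Each iteration draws equal-size subsamples (size `min(n_a, n_b)`, without
#' replacement) from both groups — neutralizing unbalanced group sizes —
#' pools them, permutes the group labels, and records the null mean
#' difference. The two-sided p-value uses the add-one estimator
#' `p = (1 + #{|null| >= |observed|}) / (1 + n_iterations)`, so `p` is never
#' exactly 0.
#'
#' @param bag_a,bag_b Numeric BAG vectors of the two groups.
#' @param n_iterations Number of subsample iterations; default 5000.
#' @param seed Integer seed.
#' @return An object of class `permutation_result`: `observed_diff`,
#'   `n_iterations`, `subsample_size`, `p_two_sided`, `null_summary`, `seed`.
#' @export
permutation_group_test <- function(bag_a, bag_b, n_iterations = 5000, seed = 1L) {
  if (!length(bag_a) || !length(bag_b)) {
    stop_brainclock("both groups must be non-empty", class = "brainclock_input_error")
  }
  if (n_iterations < 100) {
    warning("fewer than 100 permutation iterations: p-values will be coarse")
  }
  m <- min(length(bag_a), length(bag_b))
  observed <- mean(bag_a) - mean(bag_b)
  null_diff <- numeric(n_iterations)
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      sa <- if (length(bag_a) == m) bag_a else bag_a[sample.int(length(bag_a), m)]
      sb <- if (length(bag_b) == m) bag_b else bag_b[sample.int(length(bag_b), m)]
      pooled <- c(sa, sb)
      perm <- sample.int(2L * m)
      null_diff[it] <- mean(pooled[perm[seq_len(m)]]) -
        mean(pooled[perm[seq.int(m + 1L, 2L * m)]])
    }
  })
  p <- (1 + sum(abs(null_diff) >= abs(observed))) / (1 + n_iterations)
  structure(
    list(observed_diff = observed, n_iterations = as.integer(n_iterations),
         subsample_size = as.integer(m), p_two_sided = p,
         null_summary = c(mean = mean(null_diff), sd = sd(null_diff),
                          quantile(null_diff, c(0.025, 0.5, 0.975))),
         seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> diff=%.3f years  p=%.4g  (%d iterations, subsample %d)\n",
    x$observed_diff, x$p_two_sided, x$n_iterations, x$subsample_size))
  invisible(x)
}

#' Adjust BAGs for covariates by OLS residualization
#'
#' Regresses BAG on the covariate columns (with intercept, pooled across
#' groups) and returns the residuals, which are exactly orthogonal to every
#' retained covariate. Collinear columns are dropped with a warning.
#'
#' @param bags Numeric BAG vector.
#' @param covariates Data frame or matrix of numeric covariates (no missing
#'   values), rows matching `bags`.
#' @return Numeric vector of adjusted BAGs (residuals, sum exactly 0).
#' @export
covariate_adjust <- function(bags, covariates) {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (anyNA(X) || anyNA(bags)) {
    stop_brainclock("covariates and bags must not contain missing values",
                    class = "brainclock_input_error")
  }
  if (nrow(X) != length(bags)) {
    stop_brainclock("covariate rows (%d) do not match bags (%d)",
                    nrow(X), length(bags), class = "brainclock_input_error")
  }
  M <- cbind(`(Intercept)` = 1, X)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    keep <- qr_m$pivot[seq_len(qr_m$rank)]
    dropped <- setdiff(colnames(M), colnames(M)[keep])
    warning(sprintf("dropping collinear covariate(s): %s",
                    paste(dropped, collapse = ", ")))
    M <- M[, sort(keep), drop = FALSE]
    qr_m <- qr(M)
  }
  as.numeric(bags - M %*% qr.coef(qr_m, bags))
}

#' Within-scanner BAG harmonization (sign-preserving max-abs scaling)
#'
#' Within each scanner, BAGs are divided by the scanner's maximum absolute
#' BAG, mapping values into `[-1, 1]` while preserving signs, zeros, and the
#' within-scanner rank order. Scanners whose BAGs are all zero pass through
#' unchanged.
#'
#' @param bags Numeric BAG vector.
#' @param scanner_labels Scanner/site label per subject.
#' @return Numeric vector of harmonized BAGs.
#' @export
harmonize_by_scanner <- function(bags, scanner_labels) {
  stopifnot(length(bags) == length(scanner_labels))
  out <- as.numeric(bags)
  for (sc in unique(scanner_labels)) {
    idx <- which(scanner_labels == sc)
    mx <- max(abs(out[idx]))
    if (mx > 0) out[idx] <- out[idx] / mx
  }
  out
}
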