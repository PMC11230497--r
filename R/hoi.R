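# Higher-order interactions: pairwise-versus-rest O-information estimated
# with Gaussian copula entropies.
#
# For regions i and j, the statistic is the O-information of the triple
# (x_i, x_j, Z) where Z is the joint multivariate block of every other
# region:
#
#   Omega(x, y, Z) = H(x,y,Z) - H(x,y) - H(x,Z) - H(y,Z) + H(x) + H(y) + H(Z)
#
# Omega > 0 indicates redundancy-dominated interdependence (shared
# randomness), Omega < 0 synergy-dominated (collective constraints).
# Entropies are differential Shannon entropies in nats, estimated from the
# covariance of rank-Gaussianized (copula-transformed) data.

RIDGE_EPS <- 1e-8

#' Gaussian copula transform
#'
#' Rank-transforms every variable (row) to `rank/(n+1)` with average ranks
#' for ties, then maps through the standard normal quantile function. The
#' result has standard-normal order statistics as marginals while the copula
#' (the dependence structure) of the input is preserved, so the transform is
#' invariant to strictly increasing maps of individual variables.
#'
#' @param X Numeric matrix, variables x samples, or a [region_timeseries].
#' @return Matrix of the same shape as the input values.
#' @examples
#' copula_transform(matrix(c(10, 20, 30), 1, 3))
#' @export
copula_transform <- function(X) {
  if (inherits(X, "region_timeseries")) X <- X$values
  X <- as.matrix(X)
  n <- ncol(X)
  labels <- rownames(X) %||% sprintf("row %d", seq_len(nrow(X)))
  out <- matrix(0, nrow(X), n, dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (length(unique(x)) < 3L) {
      stop_brainclock(
        "degenerate channel '%s': fewer than 3 distinct values", labels[i],
        class = "brainclock_degenerate_channel"
      )
    }
    out[i, ] <- qnorm(rank(x, ties.method = "average") / (n + 1))
  }
  out
}

# log-determinant via Cholesky with a ridge fallback for singular covariances
logdet_cov <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance: adding ridge 1e-8 to the diagonal")
    ch <- chol(S + diag(RIDGE_EPS, nrow(S)))
  }
  2 * sum(log(diag(ch)))
}

#' Gaussian differential entropy of a (copula-transformed) block
#'
#' Computes `0.5 * ln((2*pi*e)^k * det(Sigma))` in nats, with `Sigma` the
#' sample covariance of the k-variable block. Near-singular covariances are
#' regularized with a `1e-8` diagonal ridge (with a warning).
#'
#' @param block Numeric matrix, variables x samples, already
#'   copula-transformed (or otherwise approximately Gaussian).
#' @return An object of class `entropy_estimate` with fields `value` (nats),
#'   `block_size`, and `covariance_log_det`.
#' @examples
#' x <- copula_transform(matrix(rnorm(2000), 1))
#' gaussian_entropy(x)$value  # close to 0.5 * log(2 * pi * exp(1))
#' @export
gaussian_entropy <- function(block) {
  block <- as.matrix(block)
  k <- nrow(block)
  if (ncol(block) <= k) {
    stop_brainclock("entropy estimation needs more samples (%d) than variables (%d)",
                    ncol(block), k, class = "brainclock_input_error")
  }
  S <- cov(t(block))
  ld <- logdet_cov(S)
  structure(
    list(value = 0.5 * (k * log(2 * pi * exp(1)) + ld),
         block_size = k, covariance_log_det = ld),
    class = "entropy_estimate"
  )
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> k=%d H=%.4f nats\n", x$block_size, x$value))
  invisible(x)
}

# Entropy terms for a joint Gaussian with covariance S (no data needed);
# internal, used by the closed-form oracle tests as well.
gaussian_entropy_from_cov <- function(S) {
  S <- as.matrix(S)
  k <- nrow(S)
  0.5 * (k * log(2 * pi * exp(1)) + logdet_cov(S))
}

#' n-variable O-information (general form)
#'
#' The full multivariate O-information of an n-variable system:
#' `(n - 2) * H(X) + sum_j [H(X_j) - H(X_{-j})]`, each variable treated as
#' univariate. Estimated with Gaussian copula entropies. For `n = 3` this is
#' algebraically identical to the inclusion-exclusion triple expression used
#' by [o_information_pair()].
#'
#' @param X Variables x samples matrix or [region_timeseries].
#' @param copula Transform the data first? Set `FALSE` if `X` is already
#'   copula-transformed.
#' @return O-information in nats.
#' @export
o_information <- function(X, copula = TRUE) {
  if (inherits(X, "region_timeseries")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) {
    stop_brainclock("O-information needs at least 3 variables",
                    class = "brainclock_input_error")
  }
  G <- if (copula) copula_transform(X) else X
  S <- cov(t(G))
  # all terms reduce to log-determinants; the (2*pi*e) constants cancel:
  # (n-2) * k_n + sum_j (1 - (n-1)) = (n-2)*n + n - n*(n-1) = 0
  ld_full <- logdet_cov(S)
  total <- (n - 2) * 0.5 * ld_full
  for (j in seq_len(n)) {
    total <- total + 0.5 * log(S[j, j]) - 0.5 * logdet_cov(S[-j, -j, drop = FALSE])
  }
  total
}

#' Pairwise-versus-rest O-information for one region pair
#'
#' O-information of the triple `(x_i, x_j, Z)` where `Z` is the joint block
#' of all remaining regions (treated as one multivariate variable, not a bag
#' of univariate terms). Symmetric in `(i, j)`.
#'
#' @param ts A [region_timeseries] (or variables x samples matrix).
#' @param i,j Region indices (or labels), `i != j`.
#' @param copula Transform the data first?
#' @return O-information in nats; positive = redundancy, negative = synergy.
#' @export
o_information_pair <- function(ts, i, j, copula = TRUE) {
  X <- if (inherits(ts, "region_timeseries")) ts$values else as.matrix(ts)
  if (is.character(i)) i <- match(i, rownames(X))
  if (is.character(j)) j <- match(j, rownames(X))
  n <- nrow(X)
  if (n < 3L) {
    stop_brainclock("need at least 3 regions", class = "brainclock_input_error")
  }
  if (anyNA(c(i, j)) || i < 1 || j < 1 || i > n || j > n || i == j) {
    stop_brainclock("invalid region pair (%s, %s)", i, j,
                    class = "brainclock_input_error")
  }
  G <- if (copula) copula_transform(X) else X
  S <- cov(t(G))
  omega_from_cov(S, i, j)
}

# Omega(i, j | rest) from a full covariance matrix. Shared with the fast
# whole-matrix path; constants cancel so only log-determinants remain.
omega_from_cov <- function(S, i, j) {
  rest <- setdiff(seq_len(nrow(S)), c(i, j))
  0.5 * (
    logdet_cov(S) -
      logdet_cov(S[c(i, j), c(i, j), drop = FALSE]) -
      logdet_cov(S[-j, -j, drop = FALSE]) -
      logdet_cov(S[-i, -i, drop = FALSE]) +
      log(S[i, i]) + log(S[j, j]) +
      logdet_cov(S[rest, rest, drop = FALSE])
  )
}

#' Pairwise-versus-rest O-information matrix
#'
#' Computes the full N x N matrix with entry `(i, j)` equal to
#' [o_information_pair()] for every pair, using a shared-computation path:
#' all required log-determinants of principal submatrices are obtained from
#' one covariance factorization, via the identities
#' `det(S_{-i}) = det(S) * P_ii` and
#' `det(S_{-ij}) = det(S) * (P_ii * P_jj - P_ij^2)` with `P = S^{-1}`.
#' The result is identical (to numerical precision) to looping
#' [o_information_pair()] over all pairs.
#'
#' @param ts A [region_timeseries].
#' @return An object of class `omega_matrix`: fields `omega` (N x N, nats,
#'   zero diagonal), `normalized` (`FALSE`), `normalization_constant` (`NA`),
#'   `region_labels`, `modality`, `n_samples`.
#' @seealso [normalize_omega()], [o_information_pair()]
#' @export
omega_matrix <- function(ts) {
  if (!inherits(ts, "region_timeseries")) {
    ts <- region_timeseries(ts)
  }
  X <- ts$values
  n <- nrow(X)
  G <- copula_transform(X)
  S <- cov(t(G))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular covariance: adding ridge 1e-8 to the diagonal")
    S <- S + diag(RIDGE_EPS, n)
    ch <- chol(S)
  }
  ld_full <- 2 * sum(log(diag(ch)))
  P <- chol2inv(ch)
  # log det of the (N-1)-dim principal submatrix dropping i
  ld_drop1 <- ld_full + log(diag(P))
  lvar <- log(diag(S))
  om <- matrix(0, n, n, dimnames = list(ts$region_labels, ts$region_labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      det2_P <- P[i, i] * P[j, j] - P[i, j]^2 # det of 2x2 block of S^{-1}
      ld_drop_ij <- ld_full + log(max(det2_P, .Machine$double.xmin))
      ld_pair <- log(max(S[i, i] * S[j, j] - S[i, j]^2, .Machine$double.xmin))
      val <- 0.5 * (ld_full - ld_pair - ld_drop1[j] - ld_drop1[i] +
                      lvar[i] + lvar[j] + ld_drop_ij)
      om[i, j] <- val
      om[j, i] <- val
    }
  }
  structure(
    list(omega = om, normalized = FALSE, normalization_constant = NA_real_,
         region_labels = ts$region_labels, modality = ts$modality,
         n_samples = ncol(X)),
    class = "omega_matrix"
  )
}

#' Normalize an O-information matrix to the unit interval
#'
#' Divides every entry by the maximum absolute off-diagonal value of the same
#' matrix, so the normalized matrix has entries in `[-1, 1]` with signs (and
#' zeros) preserved. An all-zero matrix is returned unchanged with
#' `normalization_constant = 0`.
#'
#' @param m An `omega_matrix` (raw).
#' @return The matrix with `normalized = TRUE` and the constant recorded.
#' @export
normalize_omega <- function(m) {
  stopifnot(inherits(m, "omega_matrix"))
  if (isTRUE(m$normalized)) {
    warning("omega matrix is already normalized; returning unchanged")
    return(m)
  }
  cst <- max(abs(m$omega))
  if (cst > 0) m$omega <- m$omega / cst
  m$normalized <- TRUE
  m$normalization_constant <- cst
  m
}

#' @export
print.omega_matrix <- function(x, ...) {
  cat(sprintf("<omega_matrix> %d regions (%s, %d samples)%s\n",
              nrow(x$omega), x$modality, x$n_samples,
              if (isTRUE(x$normalized)) " [normalized]" else ""))
  off <- x$omega[upper.tri(x$omega)]
  cat(sprintf("  off-diagonal range: [%.4f, %.4f]\n", min(off), max(off)))
  invisible(x)
}
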