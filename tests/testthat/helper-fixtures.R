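# Shared fixtures, all generated in code at test time.

# Small, fast cohort config used across module tests.
small_cohort_config <- function(n_subjects = 20, seed = 101, n_samples = 160,
                                ...) {
  suppressWarnings(cohort_config(
    n_subjects = n_subjects, n_regions = 8, n_samples = n_samples,
    n_blocks = 2, seed = seed, ...
  ))
}

# Gaussian data with an exact sample covariance (for entropy oracles):
# whiten empirically, then color with chol(Sigma).
exact_cov_gaussian <- function(Sigma, n, seed = 1) {
  k <- nrow(Sigma)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  Z <- withr_seed(matrix(rnorm(k * n), k, n))
  Z <- Z - rowMeans(Z)
  W <- t(chol(cov(t(Z))))          # empirical whitening
  Z <- solve(W, Z)
  t(chol(Sigma)) %*% Z
}

# Population O-information of a trivariate Gaussian from its correlation
# matrix (closed form; independent oracle for the consistency tests).
omega_trivariate_gaussian <- function(R) {
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus
  0.5 * (ld(R) - ld(R[1:2, 1:2]) - ld(R[c(1, 3), c(1, 3)]) -
           ld(R[2:3, 2:3]) + 0 + 0 + 0)
}

# Brute-force pairwise-vs-rest Omega matrix: every entropy recomputed from
# first principles on the copula-transformed data (no covariance-inverse
# shortcuts). Oracle for omega_matrix().
brute_force_omega <- function(ts) {
  G <- copula_transform(ts)
  n <- nrow(G)
  H <- function(rows) gaussian_entropy(G[rows, , drop = FALSE])$value
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      rest <- setdiff(seq_len(n), c(i, j))
      val <- H(seq_len(n)) - H(c(i, j)) - H(setdiff(seq_len(n), j)) -
        H(setdiff(seq_len(n), i)) + H(i) + H(j) + H(rest)
      out[i, j] <- val
      out[j, i] <- val
    }
  }
  out
}

# Minimal hand-built brain graph (bypasses omega estimation).
manual_graph <- function(A, X = A, age = 50, id = "g", labels = NULL,
                         modality = "fMRI") {
  structure(
    list(adjacency = A, node_features = X, target_age = age, subject_id = id,
         meta = list(subject_id = id, age = age, diagnosis = "HC"),
         region_labels = labels %||% sprintf("R%03d", seq_len(nrow(A))),
         modality = modality, is_augmented = FALSE, parent_ids = NULL,
         alpha = NULL),
    class = "brain_graph"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Graphs with a planted linear age signal, cheap to train on. The adjacency
# carries an age-dependent offset on a fixed support plus noise.
toy_age_graphs <- function(n = 40, n_nodes = 8, seed = 7) {
  set.seed(seed)
  ages <- runif(n, 40, 90)
  lapply(seq_len(n), function(k) {
    base <- 0.5 - 0.004 * (ages[k] - 40)
    A <- matrix(rnorm(n_nodes^2, sd = 0.03), n_nodes)
    A <- (A + t(A)) / 2
    A[1:4, 1:4] <- A[1:4, 1:4] + base
    diag(A) <- 0
    manual_graph(A, A, age = ages[k], id = sprintf("toy-%03d", k))
  })
}

# One small trained model + split, built once per test run (caching keeps the
# suite fast; seeds are fixed so the fixture is deterministic).
fixture_env <- new.env(parent = emptyenv())

small_trained_model <- function() {
  if (!is.null(fixture_env$model)) {
    return(list(model = fixture_env$model, split = fixture_env$split))
  }
  graphs <- toy_age_graphs(n = 60, seed = 11)
  split <- stratified_split(graphs, 0.8, 4, seed = 12)
  split$train <- c(split$train,
                   augment_by_interpolation(split$train, 40, seed = 13))
  plan <- training_plan(learning_rate_grid = 1e-2, epoch_grid = 40,
                        hidden_dim = 8, batch_size = 8, seed = 14)
  fixture_env$model <- train_with_grid_search(split, plan)
  fixture_env$split <- split
  list(model = fixture_env$model, split = fixture_env$split)
}

# Deterministic EEG-like fixture passing all four quality checks: a shared
# 8 Hz rhythm plus small channel-specific 5 Hz components (band-limited,
# bounded, correlated, non-weak).
clean_eeg <- function(seconds = 10, rate = 128, channels = 16) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  X <- t(vapply(seq_len(channels), function(ch) {
    sin(2 * pi * 8 * t) + 0.3 * sin(2 * pi * 5 * t + ch / 3)
  }, numeric(length(t))))
  region_timeseries(X, modality = "EEG", rate = rate)
}
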