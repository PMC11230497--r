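# Gaussian copula O-information estimation.

test_that("copula_transform maps ranks through the normal quantile function", {
  out <- copula_transform(matrix(c(10, 20, 30), 1, 3))
  expect_equal(as.numeric(out), qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)
  # marginals are standard-normal order statistics for any input
  set.seed(1)
  X <- matrix(rexp(200), 2, 100)
  G <- copula_transform(X)
  expect_equal(sort(G[1, ]), qnorm((1:100) / 101), tolerance = 1e-12)
})

test_that("copula_transform is invariant to strictly monotone maps", {
  set.seed(2)
  X <- matrix(rnorm(300), 3, 100)
  expect_equal(copula_transform(exp(X)), copula_transform(X))
  expect_equal(copula_transform(X * 7 - 2), copula_transform(X))
})

test_that("constant channels raise a degenerate-channel error naming the region", {
  X <- rbind(a = rnorm(20), b = rep(5, 20), c = rnorm(20))
  err <- expect_error(copula_transform(X), class = "brainclock_degenerate_channel")
  expect_match(conditionMessage(err), "b")
})

test_that("gaussian_entropy matches closed forms on exact-covariance data", {
  # univariate standard normal: 0.5 * ln(2*pi*e)
  x <- exact_cov_gaussian(matrix(1, 1, 1), 5000, seed = 3)
  h1 <- gaussian_entropy(x)
  expect_equal(h1$value, 0.5 * log(2 * pi * exp(1)), tolerance = 1e-6)
  expect_equal(h1$block_size, 1L)
  # two independent standard normals: additivity
  h2 <- gaussian_entropy(exact_cov_gaussian(diag(2), 5000, seed = 4))
  expect_equal(h2$value, log(2 * pi * exp(1)), tolerance = 1e-6)
  # bivariate rho = 0.5: 2.8379 + 0.5 * ln(0.75)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  h3 <- gaussian_entropy(exact_cov_gaussian(S, 5000, seed = 5))
  expect_equal(h3$value, log(2 * pi * exp(1)) + 0.5 * log(0.75),
               tolerance = 1e-6)
})

test_that("singular covariance is ridge-regularized with a warning", {
  X <- matrix(rnorm(100), 2, 50)
  X <- rbind(X, X[1, ] + X[2, ])  # exactly collinear
  expect_warning(h <- gaussian_entropy(X), "ridge")
  expect_true(is.finite(h$value))
})

test_that("o_information_pair recovers closed-form redundancy and synergy", {
  n <- 20000
  # common driver: corr(x,y) = corr(x,z) = 1/sqrt(2), corr(y,z) = 1/2
  R_red <- rbind(c(1, 1 / sqrt(2), 1 / sqrt(2)),
                 c(1 / sqrt(2), 1, 1 / 2),
                 c(1 / sqrt(2), 1 / 2, 1))
  pop_red <- as.numeric(omega_trivariate_gaussian(R_red))
  expect_equal(pop_red, 0.5 * log(4 / 3), tolerance = 1e-12)  # +0.1438
  set.seed(6)
  x <- rnorm(n); y <- (x + rnorm(n)) / sqrt(2); z <- (x + rnorm(n)) / sqrt(2)
  expect_lt(abs(o_information_pair(rbind(x, y, z), 2, 3) - pop_red), 0.03)
  # noisy sum: z = (x + y + eps)/sqrt(3) is synergy-dominated
  R_syn <- rbind(c(1, 0, 1 / sqrt(3)),
                 c(0, 1, 1 / sqrt(3)),
                 c(1 / sqrt(3), 1 / sqrt(3), 1))
  pop_syn <- as.numeric(omega_trivariate_gaussian(R_syn))
  expect_equal(pop_syn, -0.5 * log(4 / 3), tolerance = 1e-12)  # -0.1438
  set.seed(7)
  x <- rnorm(n); y <- rnorm(n); z <- (x + y + rnorm(n)) / sqrt(3)
  est <- o_information_pair(rbind(x, y, z), 1, 2)
  expect_lt(abs(est - pop_syn), 0.03)
  expect_lt(est, 0)
  # independence: all joint entropies additive, Omega ~ 0
  set.seed(8)
  indep <- matrix(rnorm(3 * n), 3)
  expect_lt(abs(o_information_pair(indep, 1, 3)), 0.02)
})

test_that("general form (n-variable) equals the triple expression for n = 3", {
  set.seed(9)
  X <- matrix(rnorm(3 * 500), 3)
  X[3, ] <- X[1, ] * 0.4 + X[3, ]
  expect_equal(o_information(X), o_information_pair(X, 1, 2),
               tolerance = 1e-10)
  expect_equal(o_information(X), o_information_pair(X, 2, 3),
               tolerance = 1e-10)
})

test_that("omega_matrix agrees with the brute-force entropy-sum oracle", {
  for (n_reg in c(4, 6)) {
    set.seed(20 + n_reg)
    X <- matrix(rnorm(n_reg * 400), n_reg)
    X[2, ] <- X[1, ] * 0.6 + X[2, ]          # plant some dependence
    X[n_reg, ] <- X[3, ] * 0.5 + X[n_reg, ]
    ts <- region_timeseries(X)
    m <- omega_matrix(ts)
    expect_equal(m$omega, brute_force_omega(ts), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_identical(m$omega, t(m$omega))
    expect_true(all(diag(m$omega) == 0))
  }
})

test_that("omega_matrix is equivariant under region permutation and monotone maps", {
  set.seed(30)
  X <- matrix(rnorm(5 * 300), 5)
  X[2, ] <- 0.5 * X[1, ] + X[2, ]
  labels <- letters[1:5]
  m <- omega_matrix(region_timeseries(X, labels))
  perm <- c(3, 1, 5, 2, 4)
  m_perm <- omega_matrix(region_timeseries(X[perm, ], labels[perm]))
  expect_equal(m_perm$omega, m$omega[perm, perm], tolerance = 1e-10)
  # strictly increasing map of one region leaves Omega unchanged
  X2 <- X
  X2[4, ] <- exp(X2[4, ])
  m_mono <- omega_matrix(region_timeseries(X2, labels))
  expect_equal(m_mono$omega, m$omega, tolerance = 1e-12)
})

test_that("independent regions give near-zero off-diagonals", {
  set.seed(31)
  m <- omega_matrix(region_timeseries(matrix(rnorm(4 * 20000), 4)))
  expect_lt(max(abs(m$omega[upper.tri(m$omega)])), 0.03)
})

test_that("synthetic block structure yields within-block > cross-block Omega", {
  cfg <- small_cohort_config()
  rec <- list(subject_id = "sub-0001", age = 45, sex = "F", diagnosis = "HC",
              region = "nonLAC", scanner = "scanner01")
  ts <- simulate_subject_timeseries(rec, cfg, seed = 5)
  m <- omega_matrix(ts)
  blocks <- rep(1:2, each = 4)
  same <- outer(blocks, blocks, "==") & upper.tri(m$omega)
  diff <- outer(blocks, blocks, "!=") & upper.tri(m$omega)
  expect_gt(mean(m$omega[same]), mean(m$omega[diff]))
})

test_that("normalize_omega bounds entries at 1, preserves signs, handles zeros", {
  set.seed(32)
  X <- matrix(rnorm(5 * 400), 5)
  X[2, ] <- X[1, ] * 0.7 + X[2, ]
  m <- omega_matrix(region_timeseries(X))
  nm <- normalize_omega(m)
  expect_true(nm$normalized)
  expect_equal(max(abs(nm$omega)), 1)
  expect_identical(sign(nm$omega), sign(m$omega))
  expect_equal(nm$omega * nm$normalization_constant, m$omega, tolerance = 1e-12)
  # all-zero matrix passes through with constant 0
  z <- m
  z$omega[] <- 0
  nz <- normalize_omega(z)
  expect_true(all(nz$omega == 0))
  expect_identical(nz$normalization_constant, 0)
  expect_warning(normalize_omega(nm), "already normalized")
})
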