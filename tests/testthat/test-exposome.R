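# Gradient-boosting BAG regressions and multi-method importance.

make_design <- function(n = 300, gini_slope = 0.3, diagnosis_offset = 6,
                        noise_sd = 3, seed = 41) {
  cfg <- small_cohort_config(n_subjects = n, seed = seed)
  cohort <- generate_cohort_table(cfg)
  countries <- unique(cohort$country)
  expo <- generate_exposome_table(countries, seed = seed + 1,
                                  gini_slope = gini_slope,
                                  diagnosis_offset = diagnosis_offset)
  bag <- simulate_planted_bag(cohort, expo, noise_sd = noise_sd,
                              seed = seed + 2)
  suppressWarnings(exposome_design(cohort, expo, bag))
}

test_that("gbrt fits exact and null signals as expected", {
  set.seed(1)
  X <- data.frame(gini = runif(300, 25, 55), junk = rnorm(300))
  # deterministic signal: near-perfect CV fit
  d_exact <- structure(list(X = as.matrix(X), bag = 2 * X$gini,
                            predictors = colnames(X)),
                       class = "exposome_design")
  fit <- fit_bag_regression(d_exact, n_folds = 10, n_repeats = 2, seed = 2,
                            grid = data.frame(n_trees = 200, max_depth = 3,
                                              learning_rate = 0.1))
  expect_gte(fit$cv_r2, 0.95)
  expect_equal(nrow(fit$metrics), 20)  # n_folds x n_repeats rows
  # pure noise: no generalization
  d_null <- structure(list(X = as.matrix(X), bag = rnorm(300),
                           predictors = colnames(X)),
                      class = "exposome_design")
  fit0 <- fit_bag_regression(d_null, n_folds = 10, n_repeats = 2, seed = 3,
                             grid = data.frame(n_trees = 50, max_depth = 2,
                                               learning_rate = 0.1))
  expect_lte(fit0$cv_r2, 0.1)
  # constant outcome errors
  d_const <- structure(list(X = as.matrix(X), bag = rep(1, 300),
                            predictors = colnames(X)),
                       class = "exposome_design")
  expect_error(fit_bag_regression(d_const, seed = 1),
               class = "brainclock_input_error")
})

test_that("gbrt predictions are deterministic and respect feature names", {
  set.seed(4)
  X <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- X$a * 3 + rnorm(100, sd = 0.1)
  m1 <- gbrt_fit(X, y, n_trees = 50)
  m2 <- gbrt_fit(X, y, n_trees = 50)
  expect_identical(predict(m1, X), predict(m2, X))
  # column order at predict time must not matter
  expect_identical(predict(m1, X[, c("b", "a")]), predict(m1, X))
  expect_gt(cor(predict(m1, X), y), 0.95)
})

test_that("exposome design encodes contrasts and validates the join", {
  cfg <- small_cohort_config(n_subjects = 50, seed = 42)
  cohort <- generate_cohort_table(cfg)
  expo <- generate_exposome_table(unique(cohort$country), seed = 1)
  expect_warning(d <- exposome_design(cohort, expo, rep(0.5, 50)),
                 "ecological")
  expect_setequal(colnames(d$X), c("gini", "pm25", "comm_burden",
                                   "noncomm_burden", "diagnosis_any"))
  expect_true(all(d$X[, "diagnosis_any"] %in% c(0, 1)))
  expect_equal(unname(d$X[, "diagnosis_any"]),
               as.numeric(cohort$diagnosis != "HC"))
  cohort$country[1] <- "Atlantis"
  expect_error(suppressWarnings(exposome_design(cohort, expo, rep(0.5, 50))),
               class = "brainclock_input_error")
})

test_that("a dominant feature ranks first under both required methods", {
  set.seed(5)
  n <- 250
  X <- data.frame(strong = runif(n), w1 = rnorm(n), w2 = rnorm(n))
  d <- structure(list(X = as.matrix(X), bag = 10 * X$strong + rnorm(n, sd = 0.1),
                      predictors = colnames(X)),
                 class = "exposome_design")
  fit <- fit_bag_regression(d, n_folds = 10, n_repeats = 1, seed = 6,
                            grid = data.frame(n_trees = 100, max_depth = 2,
                                              learning_rate = 0.1))
  imp <- multi_method_importance(fit, n_perm_repeats = 30, n_mdi_refits = 20,
                                 seed = 7)
  for (meth in c("permutation", "mdi")) {
    sub <- imp[imp$method == meth, ]
    expect_equal(sub$predictor[which.max(sub$mean)], "strong")
    expect_true(sub$significant[sub$predictor == "strong"])
  }
})

test_that("permutation importance of a null column concentrates at zero", {
  # a feature independent of the outcome should have its CI cover zero in
  # the vast majority of null fixtures
  covered <- 0
  n_fix <- 12
  for (k in seq_len(n_fix)) {
    set.seed(100 + k)
    n <- 150
    X <- data.frame(signal = runif(n), null_col = rnorm(n))
    d <- structure(list(X = as.matrix(X),
                        bag = 5 * X$signal + rnorm(n, sd = 0.5),
                        predictors = colnames(X)),
                   class = "exposome_design")
    fit <- fit_bag_regression(d, n_folds = 10, n_repeats = 1, seed = k,
                              grid = data.frame(n_trees = 60, max_depth = 2,
                                                learning_rate = 0.1))
    imp <- multi_method_importance(fit, n_perm_repeats = 40, n_mdi_refits = 5,
                                   seed = k)
    row <- imp[imp$method == "permutation" & imp$predictor == "null_col", ]
    if (row$ci_low <= 0) covered <- covered + 1
  }
  expect_gte(covered, n_fix - 1)
})

test_that("importance summaries are seed-deterministic and f2 matches evaluation", {
  d <- make_design(n = 150, seed = 61)
  fit <- fit_bag_regression(d, n_folds = 10, n_repeats = 2, seed = 8,
                            grid = data.frame(n_trees = 80, max_depth = 2,
                                              learning_rate = 0.1))
  expect_equal(fit$metrics$f2, cohens_f2(fit$metrics$r2), tolerance = 1e-12)
  i1 <- multi_method_importance(fit, n_perm_repeats = 20, n_mdi_refits = 10,
                                seed = 9)
  i2 <- multi_method_importance(fit, n_perm_repeats = 20, n_mdi_refits = 10,
                                seed = 9)
  expect_identical(i1, i2)
})
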