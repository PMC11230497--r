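# Synthetic cohort generator.

test_that("cohort tables are deterministic and respect configured mixes", {
  cfg <- small_cohort_config(n_subjects = 100, seed = 7)
  t1 <- generate_cohort_table(cfg)
  t2 <- generate_cohort_table(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 100)
  expect_true(all(t1$age >= cfg$age_range[1] & t1$age <= cfg$age_range[2]))
  # proportions within +-2 subjects of the request (largest remainder)
  for (g in names(cfg$group_mix)) {
    expect_lte(abs(sum(t1$diagnosis == g) - 100 * cfg$group_mix[[g]]), 2)
  }
  # degenerate mix
  cfg_hc <- small_cohort_config(group_mix = c(HC = 1.0))
  expect_true(all(generate_cohort_table(cfg_hc)$diagnosis == "HC"))
})

test_that("largest-remainder allocation hits exact counts on even mixes", {
  cfg <- small_cohort_config(n_subjects = 1000,
                             group_mix = c(HC = 0.5, AD = 0.5),
                             group_age_offset = c(HC = 0, AD = 8))
  tab <- generate_cohort_table(cfg)
  expect_true(sum(tab$diagnosis == "AD") >= 498 &&
                sum(tab$diagnosis == "AD") <= 502)
})

test_that("invalid proportions raise a configuration error", {
  expect_error(small_cohort_config(group_mix = c(HC = 0.7, AD = 0.7)),
               class = "brainclock_config_error")
  expect_error(small_cohort_config(region_mix = c(LAC = 1.2, nonLAC = -0.2)),
               class = "brainclock_config_error")
  expect_error(suppressWarnings(cohort_config(n_regions = 3)),
               class = "brainclock_config_error")
  expect_error(suppressWarnings(cohort_config(age_range = c(90, 40))),
               class = "brainclock_config_error")
})

test_that("coupling profile anchors at lambda0 and never increases with age", {
  cfg <- small_cohort_config()
  expect_equal(coupling_profile(cfg$age_range[1], cfg)$lambda, cfg$lambda0)
  ages <- seq(cfg$age_range[1], cfg$age_range[2] + 20, by = 1)
  lam <- vapply(ages, function(a) coupling_profile(a, cfg)$lambda, numeric(1))
  mu <- vapply(ages, function(a) coupling_profile(a, cfg)$mu, numeric(1))
  expect_true(all(diff(lam) <= 0))
  expect_true(all(diff(mu) <= 0))
  expect_true(all(lam > 0) && all(mu > 0))
})

test_that("effective age stacks diagnosis and region offsets", {
  cfg <- small_cohort_config()
  base <- list(age = 60, sex = "M", diagnosis = "HC", region = "nonLAC")
  expect_equal(effective_age(base, cfg), 60)
  ad <- modifyList(base, list(diagnosis = "AD"))
  expect_equal(effective_age(ad, cfg), 60 + cfg$group_age_offset[["AD"]])
  lac <- modifyList(base, list(region = "LAC"))
  expect_equal(effective_age(lac, cfg), 60 + cfg$lac_extra_offset)
})

test_that("subject simulation is seed-deterministic", {
  cfg <- small_cohort_config()
  rec <- list(subject_id = "sub-0001", age = 50, sex = "F", diagnosis = "HC",
              region = "LAC", scanner = "scanner02")
  a <- simulate_subject_timeseries(rec, cfg, seed = 42)
  b <- simulate_subject_timeseries(rec, cfg, seed = 42)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(8, 160))
})

test_that("within-block coupling declines from age 20 to age 80", {
  cfg <- small_cohort_config(age_range = c(20, 80), n_samples = 400)
  mk <- function(age) {
    rec <- list(subject_id = "sub-0001", age = age, sex = "M",
                diagnosis = "HC", region = "nonLAC", scanner = "scanner01")
    simulate_subject_timeseries(rec, cfg, seed = 77)
  }
  mean_within <- function(ts) {
    cm <- cor(t(ts$values))
    blocks <- rep(1:2, each = 4)
    mean(cm[outer(blocks, blocks, "==") & upper.tri(cm)])
  }
  expect_gt(mean_within(mk(20)), mean_within(mk(80)))
})

test_that("scanner scale multiplies the signal", {
  cfg <- small_cohort_config()
  rec1 <- list(subject_id = "sub-0001", age = 50, sex = "F", diagnosis = "HC",
               region = "LAC", scanner = "scanner01")
  rec2 <- modifyList(rec1, list(scanner = "scanner02"))
  a <- simulate_subject_timeseries(rec1, cfg, seed = 5)
  b <- simulate_subject_timeseries(rec2, cfg, seed = 5)
  expect_equal(b$values / a$values,
               matrix(cfg$scanner_scale[2] / cfg$scanner_scale[1], 8, 160),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("planted synergy shifts the donor pair's Omega downward", {
  rec <- list(subject_id = "sub-0001", age = 45, sex = "M", diagnosis = "HC",
              region = "nonLAC", scanner = "scanner01")
  cfg_syn <- small_cohort_config(plant_synergy = TRUE, n_samples = 800)
  cfg_plain <- small_cohort_config(plant_synergy = FALSE, n_samples = 800)
  # region 3 = (region1 + region5 + eps)/sqrt(3): the (1,5) pair becomes
  # synergistic with respect to the rest block, which now contains their sum
  om_syn <- omega_matrix(simulate_subject_timeseries(rec, cfg_syn, seed = 9))
  om_plain <- omega_matrix(simulate_subject_timeseries(rec, cfg_plain, seed = 9))
  expect_lt(om_syn$omega[1, 5], om_plain$omega[1, 5])
})

test_that("exposome tables are deterministic with planted effects recoverable", {
  countries <- c(LETTERS[1:10])
  e1 <- generate_exposome_table(countries, seed = 3)
  e2 <- generate_exposome_table(countries, seed = 3)
  expect_identical(e1, e2)
  expect_named(e1, c("country", "gini", "pm25", "comm_burden",
                     "noncomm_burden", "gii"))
  cfg <- small_cohort_config(n_subjects = 500, seed = 8)
  cohort <- generate_cohort_table(cfg)
  cohort$country <- sample(countries, 500, replace = TRUE)
  # zero planted effects: BAG independent of GINI
  e0 <- generate_exposome_table(countries, seed = 3, gini_slope = 0,
                                diagnosis_offset = 0)
  bag0 <- simulate_planted_bag(cohort, e0, seed = 21)
  expect_lt(abs(cor(bag0, e0$gini[match(cohort$country, e0$country)])), 0.1)
  # planted slope 0.3 recovered by OLS within +-0.1
  bag <- simulate_planted_bag(cohort, e1, seed = 22)
  gini <- e1$gini[match(cohort$country, e1$country)]
  is_hc <- cohort$diagnosis == "HC"
  slope <- coef(lm(bag[is_hc] ~ gini[is_hc]))[2]
  expect_equal(unname(slope), 0.3, tolerance = 0.1)
})

test_that("fixture sets round-trip bit-exactly with a complete manifest", {
  cfg <- small_cohort_config(n_subjects = 3, seed = 55)
  out <- withr::local_tempdir()
  manifest <- write_fixture_set(cfg, out)
  expect_equal(nrow(manifest), 3 + 2)
  expect_true(all(file.exists(manifest$path)))
  expect_true(file.exists(file.path(out, "manifest.json")))
  cohort <- generate_cohort_table(cfg)
  ts <- simulate_subject_timeseries(cohort[1, ], cfg)
  back <- read_timeseries_matrix(manifest$path[1])
  expect_identical(back$values, ts$values)
  # checksum changes iff content changes
  md5_before <- tools::md5sum(manifest$path[1])
  writeLines(c(readLines(manifest$path[1]), ""), manifest$path[1])
  expect_false(identical(md5_before, tools::md5sum(manifest$path[1])))
})
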