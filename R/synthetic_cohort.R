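# Synthetic cohorts of parcellated time series and metadata.
#
# Generative model (documented in detail in the methods vignette):
# regions are partitioned into B blocks ("hub" communities). Region r in
# block b at time t is
#
#   x_r(t) = lambda(ea) * f_b(t) + mu(ea) * g(t) + noise_sd * eps_r(t)
#
# with f_b block-specific latent factors, g a global (long-range) factor,
# eps white Gaussian noise, and ea the subject's *effective age*:
#
#   ea = age + group_age_offset[diagnosis] + lac_extra_offset * 1[region == LAC]
#
# Within-block loading lambda and cross-block loading mu both decline
# linearly with effective age (floored above zero), so older (or clinical)
# brains show weaker, less redundant coupling. Shared latent factors induce
# Omega > 0 (redundancy) within blocks; an optional planted synergy triplet
# (z proportional to x + y + noise) can be switched on. Per-scanner
# multiplicative scale is applied last.

LAC_COUNTRIES <- c("Argentina", "Chile", "Colombia", "Mexico", "Peru")
NONLAC_COUNTRIES <- c("USA", "China", "Japan")

#' Configuration of a synthetic cohort
#'
#' Fixes every knob of the synthetic-data generator. Defaults emulate a
#' desk-scale version of a multi-site dementia cohort: 82 AAL-style regions,
#' fMRI-like recordings of 300 volumes (TR 2 s) or EEG-like recordings of
#' 2560 samples (5 s at 512 Hz), uniform ages, a healthy-control majority
#' with MCI/AD/bvFTD minorities carrying positive effective-age offsets, and
#' a LAC/non-LAC split with an extra LAC offset.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of parcellated regions (default 82).
#' @param n_samples Time samples per subject; default 300 for fMRI, 2560 for
#'   EEG.
#' @param modality `"fMRI"` or `"EEG"`.
#' @param tr fMRI repetition time, seconds.
#' @param rate EEG sampling rate, Hz.
#' @param age_range Chronological age range in years, `c(min, max)`.
#' @param group_mix Named proportions over diagnoses HC/MCI/AD/bvFTD
#'   (must sum to 1). Defaults mirror a control-majority clinical cohort.
#' @param group_age_offset Named years of effective brain-age shift per
#'   diagnosis.
#' @param region_mix Named proportions over `LAC`/`nonLAC`.
#' @param lac_extra_offset Extra effective-age years for LAC subjects.
#' @param n_blocks Number of latent coupling blocks (hub communities).
#' @param lambda0 Within-block factor loading at the youngest effective age.
#' @param coupling_slope Per-year decline of the within-block loading.
#' @param cross0 Cross-block (global factor) loading at the youngest age.
#' @param cross_slope Per-year decline of the cross-block loading.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param n_scanners Number of scanners/sites.
#' @param scanner_scale Multiplicative per-scanner signal scale (recycled to
#'   `n_scanners`).
#' @param plant_synergy If `TRUE`, region 3 is replaced by a noisy sum of
#'   regions 1 and 2 from different blocks, planting a synergistic triplet.
#' @param sex_region_interaction If `TRUE`, LAC females receive one extra
#'   effective-age year (qualitative stand-in for sex-by-region effects).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_subjects = 10, n_regions = 8, n_samples = 120)
#' @export
cohort_config <- function(n_subjects = 100,
                          n_regions = 82,
                          n_samples = if (modality == "fMRI") 300 else 2560,
                          modality = c("fMRI", "EEG"),
                          tr = 2,
                          rate = 512,
                          age_range = c(40, 90),
                          group_mix = c(HC = 0.66, MCI = 0.10, AD = 0.15, bvFTD = 0.09),
                          group_age_offset = c(HC = 0, MCI = 4, AD = 8, bvFTD = 7),
                          region_mix = c(LAC = 0.5, nonLAC = 0.5),
                          lac_extra_offset = 3,
                          n_blocks = 4,
                          lambda0 = 0.9,
                          coupling_slope = 0.008,
                          cross0 = 0.45,
                          cross_slope = 0.006,
                          noise_sd = 1,
                          n_scanners = 3,
                          scanner_scale = c(1, 1.15, 0.9),
                          plant_synergy = FALSE,
                          sex_region_interaction = FALSE,
                          seed = 1L) {
  modality <- match.arg(modality)
  if (!is_count(n_subjects) || !is_count(n_regions) || !is_count(n_samples) ||
      !is_count(n_blocks) || !is_count(n_scanners)) {
    stop_brainclock("counts must be positive integers",
                    class = "brainclock_config_error")
  }
  if (n_regions < 4) {
    stop_brainclock("n_regions must be >= 4", class = "brainclock_config_error")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop_brainclock("age_range must be c(min, max) with min < max",
                    class = "brainclock_config_error")
  }
  check_mix <- function(p, what, levels) {
    if (is.null(names(p)) || !all(names(p) %in% levels) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop_brainclock("%s must be named non-negative proportions over {%s} summing to 1",
                      what, paste(levels, collapse = ", "),
                      class = "brainclock_config_error")
    }
  }
  check_mix(group_mix, "group_mix", c("HC", "MCI", "AD", "bvFTD"))
  check_mix(region_mix, "region_mix", c("LAC", "nonLAC"))
  if (!all(names(group_mix) %in% names(group_age_offset))) {
    stop_brainclock("group_age_offset must cover every diagnosis in group_mix",
                    class = "brainclock_config_error")
  }
  if (n_samples < 10 * n_regions) {
    warning(sprintf(
      "n_samples (%d) < 10 x n_regions (%d); covariance estimates will be noisy",
      n_samples, 10L * n_regions
    ))
  }
  scanner_scale <- rep_len(scanner_scale, n_scanners)
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         n_samples = as.integer(n_samples), modality = modality, tr = tr,
         rate = rate, age_range = as.numeric(age_range), group_mix = group_mix,
         group_age_offset = group_age_offset, region_mix = region_mix,
         lac_extra_offset = lac_extra_offset, n_blocks = as.integer(n_blocks),
         lambda0 = lambda0, coupling_slope = coupling_slope, cross0 = cross0,
         cross_slope = cross_slope, noise_sd = noise_sd,
         n_scanners = as.integer(n_scanners), scanner_scale = scanner_scale,
         plant_synergy = isTRUE(plant_synergy),
         sex_region_interaction = isTRUE(sex_region_interaction),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Block membership of each region: contiguous, near-equal blocks.
region_blocks <- function(config) {
  sort(rep_len(seq_len(config$n_blocks), config$n_regions))
}

#' Effective age of a subject
#'
#' Chronological age plus the diagnosis offset, the LAC offset, and (if the
#' interaction flag is on) an extra year for LAC females. This is the age the
#' coupling profile sees; the gap between effective and chronological age is
#' the planted brain-age gap.
#' @param record One cohort row (list or 1-row data frame).
#' @param config A [cohort_config()].
#' @return Years.
#' @export
effective_age <- function(record, config) {
  ea <- record$age + unname(config$group_age_offset[[record$diagnosis]]) +
    config$lac_extra_offset * (record$region == "LAC")
  if (config$sex_region_interaction && record$sex == "F" && record$region == "LAC") {
    ea <- ea + 1
  }
  as.numeric(ea)
}

#' Age-dependent coupling loadings
#'
#' Within-block loading `lambda(ea) = lambda0 - coupling_slope * (ea - age_min)`
#' and cross-block loading `mu(ea) = cross0 - cross_slope * (ea - age_min)`,
#' floored at 0.05 and 0.02. At the youngest configured age,
#' `lambda = lambda0` exactly.
#' @param eff_age Effective age, years.
#' @param config A [cohort_config()].
#' @return List with `lambda` and `mu`.
#' @export
coupling_profile <- function(eff_age, config) {
  d <- eff_age - config$age_range[1]
  list(lambda = pmax(config$lambda0 - config$coupling_slope * d, 0.05),
       mu = pmax(config$cross0 - config$cross_slope * d, 0.02))
}

#' Generate a cohort metadata table
#'
#' Draws subjects with diagnosis and region counts allocated by largest
#' remainder (so realized proportions are within +-2 subjects of the
#' requested mix), ages uniform over the configured range, balanced sex,
#' country within region, scanner, eyes condition, and years of education.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `cohort_table`, one row per subject:
#'   `subject_id, age, sex, diagnosis, region, country, scanner, eyes,
#'   education, modality`.
#' @examples
#' head(generate_cohort_table(cohort_config(n_subjects = 12)))
#' @export
generate_cohort_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  with_seed(config$seed, {
    diag_counts <- largest_remainder(n, config$group_mix)
    diagnosis <- sample(rep(names(config$group_mix), diag_counts))
    region_counts <- largest_remainder(n, config$region_mix)
    region <- sample(rep(names(config$region_mix), region_counts))
    country <- ifelse(region == "LAC",
                      sample(LAC_COUNTRIES, n, replace = TRUE),
                      sample(NONLAC_COUNTRIES, n, replace = TRUE))
    tab <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      diagnosis = diagnosis,
      region = region,
      country = country,
      scanner = sprintf("scanner%02d", sample.int(config$n_scanners, n, replace = TRUE)),
      eyes = sample(c("open", "closed"), n, replace = TRUE),
      education = pmin(pmax(round(rnorm(n, 12, 3)), 0), 22),
      modality = config$modality,
      stringsAsFactors = FALSE
    )
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}

#' Simulate one subject's parcellated time series
#'
#' Latent-factor Gaussian generative model (see the module header and the
#' methods vignette): block factors with age-declining loadings, a global
#' long-range factor, additive noise, optional synergy triplet, and a
#' per-scanner multiplicative scale applied last.
#'
#' @param record One row of a [generate_cohort_table()] table (data frame row
#'   or named list).
#' @param config The [cohort_config()] used for the cohort.
#' @param seed Integer seed for this subject (defaults to a per-subject child
#'   of the config seed if the record carries a numeric suffix).
#' @return A [region_timeseries].
#' @export
simulate_subject_timeseries <- function(record, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.data.frame(record)) record <- as.list(record[1, ])
  if (is.null(seed)) {
    idx <- suppressWarnings(as.integer(gsub("\\D", "", record$subject_id %||% "0")))
    seed <- child_seed(config$seed, if (is.na(idx)) 0L else idx)
  }
  ea <- effective_age(record, config)
  cp <- coupling_profile(ea, config)
  blocks <- region_blocks(config)
  n_r <- config$n_regions
  n_t <- config$n_samples
  with_seed(seed, {
    f <- matrix(rnorm(config$n_blocks * n_t), config$n_blocks, n_t)
    g <- rnorm(n_t)
    eps <- matrix(rnorm(n_r * n_t, sd = config$noise_sd), n_r, n_t)
    X <- cp$lambda * f[blocks, , drop = FALSE] +
      matrix(cp$mu * g, n_r, n_t, byrow = TRUE) + eps
    if (config$plant_synergy && n_r >= 3) {
      # region 3 becomes a noisy sum of two regions from different blocks
      donor <- which(blocks != blocks[1])[1]
      X[3, ] <- (X[1, ] + X[donor, ] + rnorm(n_t, sd = config$noise_sd)) / sqrt(3)
    }
    sc_idx <- suppressWarnings(as.integer(gsub("\\D", "", record$scanner %||% "1")))
    if (is.na(sc_idx) || sc_idx < 1) sc_idx <- 1L
    scale <- config$scanner_scale[((sc_idx - 1L) %% config$n_scanners) + 1L]
    region_timeseries(X * scale,
                      region_labels = sprintf("R%03d", seq_len(n_r)),
                      modality = config$modality,
                      tr = if (config$modality == "fMRI") config$tr else NULL,
                      rate = if (config$modality == "EEG") config$rate else NULL)
  })
}

#' Country-level exposome table
#'
#' Generates one row per country with indicators on their customary scales:
#' `gini` (index points, ~25-55), `pm25` (annual mean µg/m^3, ~5-60),
#' `comm_burden` and `noncomm_burden` (relative disease-burden indices,
#' ~10-60), `gii` (gender inequality index, 0-1). Indicators are drawn
#' independently across countries. The attributes `gini_slope` (years of BAG
#' per GINI point) and `diagnosis_offset` (years of BAG for non-HC subjects)
#' record the planted linear effect used by [simulate_planted_bag()].
#'
#' @param countries Character vector of at least two country names.
#' @param seed Integer seed.
#' @param gini_slope Planted effect: years of expected BAG per GINI point
#'   (centred). Default 0.3.
#' @param diagnosis_offset Planted effect: years of expected BAG added for a
#'   clinical (non-HC) diagnosis. Default 6.
#' @return A `data.frame` of class `exposome_table`.
#' @export
generate_exposome_table <- function(countries, seed = 1L,
                                    gini_slope = 0.3, diagnosis_offset = 6) {
  countries <- unique(as.character(countries))
  if (length(countries) < 2) {
    stop_brainclock("need at least two countries", class = "brainclock_config_error")
  }
  with_seed(seed, {
    tab <- data.frame(
      country = countries,
      gini = round(runif(length(countries), 25, 55), 1),
      pm25 = round(runif(length(countries), 5, 60), 1),
      comm_burden = round(runif(length(countries), 10, 60), 1),
      noncomm_burden = round(runif(length(countries), 10, 60), 1),
      gii = round(runif(length(countries), 0.05, 0.70), 3),
      stringsAsFactors = FALSE
    )
    attr(tab, "gini_slope") <- gini_slope
    attr(tab, "diagnosis_offset") <- diagnosis_offset
    class(tab) <- c("exposome_table", "data.frame")
    tab
  })
}

#' Simulate brain-age gaps with planted exposome effects
#'
#' Subject-level BAG drawn as
#' `bag = gini_slope * (gini - mean(gini)) + diagnosis_offset * 1[non-HC] +
#' N(0, noise_sd)`, using the country-level GINI joined through each
#' subject's country. Used by the exposome recovery tests; with both planted
#' effects at zero the BAG is independent of every indicator.
#'
#' @param cohort A [generate_cohort_table()] table.
#' @param exposome A [generate_exposome_table()] table covering the cohort's
#'   countries.
#' @param noise_sd Residual standard deviation, years (default 3).
#' @param seed Integer seed.
#' @return Numeric vector of BAGs, one per cohort row.
#' @export
simulate_planted_bag <- function(cohort, exposome, noise_sd = 3, seed = 1L) {
  idx <- match(cohort$country, exposome$country)
  if (anyNA(idx)) {
    stop_brainclock("exposome table is missing countries: %s",
                    paste(unique(cohort$country[is.na(idx)]), collapse = ", "),
                    class = "brainclock_input_error")
  }
  gini <- exposome$gini[idx]
  slope <- attr(exposome, "gini_slope") %||% 0
  offset <- attr(exposome, "diagnosis_offset") %||% 0
  with_seed(seed, {
    slope * (gini - mean(exposome$gini)) +
      offset * (cohort$diagnosis != "HC") +
      rnorm(nrow(cohort), sd = noise_sd)
  })
}

#' Write a complete fixture set to disk
#'
#' Generates (or accepts) a cohort, writes one TSV time-series file per
#' subject plus the cohort and exposome tables, and returns a manifest with
#' MD5 checksums. Files round-trip bit-exactly through
#' [read_timeseries_matrix()].
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @param cohort Optional pre-generated cohort table.
#' @return A `data.frame` manifest (`path`, `kind`, `md5`), one row per
#'   subject file plus the cohort and exposome tables. Also written as
#'   `manifest.json` in `out_dir`.
#' @export
write_fixture_set <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      stop_brainclock("cannot create output directory '%s'", out_dir,
                      class = "brainclock_io_error")
    }
  }
  if (is.null(cohort)) cohort <- generate_cohort_table(config)
  paths <- character(0)
  kinds <- character(0)
  for (k in seq_len(nrow(cohort))) {
    ts <- simulate_subject_timeseries(cohort[k, ], config)
    p <- file.path(out_dir, paste0(cohort$subject_id[k], "_timeseries.tsv"))
    write_timeseries_matrix(ts, p)
    paths <- c(paths, p)
    kinds <- c(kinds, "timeseries")
  }
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_tsv_table(cohort, cohort_path)
  exposome <- generate_exposome_table(unique(cohort$country),
                                      seed = child_seed(config$seed, 999L))
  exposome_path <- file.path(out_dir, "exposome.tsv")
  write_tsv_table(exposome, exposome_path)
  paths <- c(paths, cohort_path, exposome_path)
  kinds <- c(kinds, "cohort", "exposome")
  manifest <- data.frame(
    path = paths, kind = kinds, md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  manifest
}
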