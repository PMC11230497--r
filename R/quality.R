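# Overall data quality (ODQ) scores.
#
# fMRI: recordings are cut into 20-TR segments; per segment and region the
# temporal signal-to-noise ratio tSNR = mean/sd is computed. A segment is
# good iff (a) the region-median tSNR exceeds the threshold (default 50),
# (b) tSNR is spatially consistent across regions (coefficient of variation
# below a ceiling), and (c) no region shows a spike (a sample further than
# k robust-SDs from the segment median). ODQ = percentage of good segments.
#
# EEG: recordings are cut into 1-second segments and four checks are applied:
# weak/constant signal (channel SD below a floor), amplitude-ratio artifacts
# (peak-to-peak over robust-SD above a ceiling), high-frequency noise
# (fraction of spectral power above a cutoff exceeding a limit), and low
# inter-channel correlation (median absolute correlation below a floor).
# A segment is good iff all four pass.

robust_sd <- function(x) 1.4826 * mad(x, constant = 1)

#' fMRI overall data quality from segment-wise tSNR
#'
#' @param ts A [region_timeseries] (fMRI).
#' @param tr Repetition time in seconds (metadata only; segmentation is by
#'   sample count).
#' @param segment_len Samples per segment; default 20 (20 TRs). Trailing
#'   partial segments are dropped.
#' @param tsnr_threshold Region-median tSNR must exceed this; default 50.
#' @param cv_threshold Max coefficient of variation of tSNR across regions;
#'   default 1.0.
#' @param spike_k Spike rule: any sample further than `spike_k` robust-SDs
#'   from its region's segment median fails the segment; default 5.
#' @return An object of class `quality_report`: `odq` (percent), `segments`
#'   (per-segment check booleans and failure reasons), thresholds.
#' @export
fmri_odq <- function(ts, tr = ts$tr %||% 2, segment_len = 20,
                     tsnr_threshold = 50, cv_threshold = 1.0, spike_k = 5) {
  stopifnot(inherits(ts, "region_timeseries"))
  X <- ts$values
  n_seg <- floor(ncol(X) / segment_len)
  if (n_seg < 1) {
    stop_brainclock("recording shorter than one %d-sample segment", segment_len,
                    class = "brainclock_input_error")
  }
  seg <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    cols <- ((s - 1L) * segment_len + 1L):(s * segment_len)
    W <- X[, cols, drop = FALSE]
    mu <- rowMeans(W)
    sdv <- apply(W, 1, sd)
    tsnr <- ifelse(sdv == 0, Inf, abs(mu) / sdv)
    ok_tsnr <- median(tsnr) > tsnr_threshold
    # spatial-consistency check on capped tSNR (zero-variance regions would
    # otherwise make the CV undefined)
    tsnr_f <- pmin(tsnr, 1e6)
    cv <- if (mean(tsnr_f) > 0) sd(tsnr_f) / mean(tsnr_f) else Inf
    ok_spatial <- cv < cv_threshold
    spike <- FALSE
    for (r in seq_len(nrow(W))) {
      rs <- robust_sd(W[r, ])
      if (rs > 0 && any(abs(W[r, ] - median(W[r, ])) > spike_k * rs)) {
        spike <- TRUE
        break
      }
    }
    seg[[s]] <- data.frame(segment = s, tsnr_median = median(tsnr_f),
                           check_tsnr = ok_tsnr, check_spatial = ok_spatial,
                           check_spike = !spike,
                           good = ok_tsnr && ok_spatial && !spike)
  }
  segments <- do.call(rbind, seg)
  segments$failed_checks <- apply(segments, 1, function(row) {
    bad <- c("tsnr", "spatial", "spike")[!as.logical(row[c("check_tsnr", "check_spatial", "check_spike")])]
    paste(bad, collapse = ",")
  })
  structure(
    list(odq = 100 * mean(segments$good), segments = segments,
         segment_length = segment_len, modality = "fMRI",
         thresholds = list(tsnr = tsnr_threshold, cv = cv_threshold,
                           spike_k = spike_k)),
    class = "quality_report"
  )
}

# fraction of spectral power (DC excluded) above `cutoff` Hz
hf_power_fraction <- function(x, rate, cutoff) {
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))^2
  half <- 2:(floor(n / 2) + 1L)           # positive frequencies
  freq <- (half - 1L) * rate / n
  tot <- sum(pw[half])
  if (tot == 0) return(0)
  sum(pw[half][freq > cutoff]) / tot
}

#' EEG overall data quality from four per-second checks
#'
#' @param ts A [region_timeseries] (EEG, channels x samples).
#' @param rate Sampling rate in Hz; defaults to the recording's metadata.
#' @param sd_floor Weak/constant-signal floor on per-channel SD; default 0.1.
#' @param ratio_ceiling Max peak-to-peak over robust-SD per channel;
#'   default 12.
#' @param hf_cutoff High-frequency cutoff in Hz; default 40. The sampling
#'   rate must exceed twice this cutoff.
#' @param hf_fraction_limit Max fraction of power above the cutoff (median
#'   across channels); default 0.5.
#' @param corr_floor Min median absolute inter-channel correlation;
#'   default 0.1.
#' @return An object of class `quality_report` with per-segment check
#'   booleans, failure reasons, and the percentage `odq`.
#' @export
eeg_odq <- function(ts, rate = ts$rate %||% 512, sd_floor = 0.1,
                    ratio_ceiling = 12, hf_cutoff = 40,
                    hf_fraction_limit = 0.5, corr_floor = 0.1) {
  stopifnot(inherits(ts, "region_timeseries"))
  if (rate <= 2 * hf_cutoff) {
    stop_brainclock("sampling rate (%g Hz) must exceed twice the high-frequency cutoff (%g Hz)",
                    rate, hf_cutoff, class = "brainclock_config_error")
  }
  X <- ts$values
  seg_len <- as.integer(round(rate))
  n_seg <- floor(ncol(X) / seg_len)
  if (n_seg < 1) {
    stop_brainclock("recording shorter than one second", class = "brainclock_input_error")
  }
  seg <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    W <- X[, ((s - 1L) * seg_len + 1L):(s * seg_len), drop = FALSE]
    sds <- apply(W, 1, sd)
    ok_sd <- all(sds >= sd_floor)
    ratios <- vapply(seq_len(nrow(W)), function(r) {
      rs <- robust_sd(W[r, ])
      if (rs == 0) Inf else diff(range(W[r, ])) / rs
    }, numeric(1))
    ok_ratio <- all(ratios <= ratio_ceiling)
    hf <- vapply(seq_len(nrow(W)), function(r) {
      hf_power_fraction(W[r, ], rate, hf_cutoff)
    }, numeric(1))
    ok_hf <- median(hf) <= hf_fraction_limit
    live <- which(sds > 0)
    ok_corr <- if (length(live) >= 2) {
      cm <- abs(cor(t(W[live, , drop = FALSE])))
      median(cm[upper.tri(cm)]) >= corr_floor
    } else {
      FALSE
    }
    seg[[s]] <- data.frame(segment = s, check_sd = ok_sd, check_ratio = ok_ratio,
                           check_hf = ok_hf, check_corr = ok_corr,
                           good = ok_sd && ok_ratio && ok_hf && ok_corr)
  }
  segments <- do.call(rbind, seg)
  segments$failed_checks <- apply(segments, 1, function(row) {
    bad <- c("weak_signal", "amplitude_ratio", "hf_noise", "low_correlation")[
      !as.logical(row[c("check_sd", "check_ratio", "check_hf", "check_corr")])]
    paste(bad, collapse = ",")
  })
  structure(
    list(odq = 100 * mean(segments$good), segments = segments,
         segment_length = seg_len, modality = "EEG",
         thresholds = list(sd_floor = sd_floor, ratio_ceiling = ratio_ceiling,
                           hf_cutoff = hf_cutoff,
                           hf_fraction_limit = hf_fraction_limit,
                           corr_floor = corr_floor)),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> %s ODQ = %.1f%% (%d segments of %d samples)\n",
              x$modality, x$odq, nrow(x$segments), x$segment_length))
  bad <- x$segments[!x$segments$good, , drop = FALSE]
  if (nrow(bad)) {
    cat(sprintf("  %d bad segment(s); first failures: %s\n", nrow(bad),
                paste(head(bad$failed_checks, 3), collapse = "; ")))
  }
  invisible(x)
}
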