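#' Parcellated region-by-time series
#'
#' Container for a parcellated recording: one row per brain region, one
#' column per time sample. This is the unit every estimator in the package
#' consumes; typical shapes are 82 regions by a few hundred fMRI volumes or
#' a few thousand EEG samples.
#'
#' @param values Numeric matrix, regions x samples. No missing values.
#' @param region_labels Character vector of unique region names, one per row.
#'   Defaults to `R001..RNNN`.
#' @param modality `"fMRI"` or `"EEG"`.
#' @param tr Repetition time in seconds (fMRI).
#' @param rate Sampling rate in Hz (EEG).
#' @return An object of class `region_timeseries`.
#' @examples
#' ts <- region_timeseries(matrix(rnorm(40), 4, 10), modality = "fMRI", tr = 2)
#' dim(ts$values)
#' @export
region_timeseries <- function(values, region_labels = NULL,
                              modality = c("fMRI", "EEG"),
                              tr = NULL, rate = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_brainclock("time-series values must be numeric", class = "brainclock_input_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_brainclock("time-series values contain missing or non-finite entries",
                    class = "brainclock_input_error")
  }
  n <- nrow(values)
  if (n < 3L) {
    stop_brainclock("at least 3 regions are required, got %d", n,
                    class = "brainclock_input_error")
  }
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(n))
  }
  region_labels <- as.character(region_labels)
  if (length(region_labels) != n || anyDuplicated(region_labels)) {
    stop_brainclock("region labels must be unique and match the number of rows",
                    class = "brainclock_input_error")
  }
  if (ncol(values) <= n) {
    warning(sprintf(
      "only %d samples for %d regions; covariance estimates may be unstable",
      ncol(values), n
    ))
  }
  rownames(values) <- region_labels
  structure(
    list(values = values, region_labels = region_labels, modality = modality,
         tr = tr, rate = rate),
    class = "region_timeseries"
  )
}

#' @export
print.region_timeseries <- function(x, ...) {
  cat(sprintf("<region_timeseries> %s: %d regions x %d samples\n",
              x$modality, nrow(x$values), ncol(x$values)))
  if (!is.null(x$tr)) cat(sprintf("  TR: %g s\n", x$tr))
  if (!is.null(x$rate)) cat(sprintf("  rate: %g Hz\n", x$rate))
  invisible(x)
}

#' @export
dim.region_timeseries <- function(x) dim(x$values)
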