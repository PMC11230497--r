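# Delimited-text I/O. All tables are TSV with header row, '.' decimal point,
# UTF-8. Numeric values are written with 17 significant digits so matrices
# round-trip bit-exactly.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", flag = "-")
  trimws(out)
}

#' Write a region time series as TSV
#'
#' First column `region`, remaining columns one per time sample. Full double
#' precision is retained so [read_timeseries_matrix()] recovers the values
#' bit-exactly.
#'
#' @param ts A [region_timeseries].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_matrix <- function(ts, path) {
  stopifnot(inherits(ts, "region_timeseries"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e) {
    stop_brainclock("cannot open '%s' for writing: %s", path, conditionMessage(e),
                    class = "brainclock_io_error")
  })
  on.exit(close(con))
  header <- c("region", sprintf("t%04d", seq_len(ncol(ts$values))))
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(ts$values))) {
    writeLines(paste(c(ts$region_labels[i], fmt_num(ts$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a region time series from TSV
#'
#' Expects a header row, a first column of unique region labels, and numeric
#' sample columns. Parsing is locale-independent; ragged rows and non-numeric
#' cells are rejected with the offending coordinates.
#'
#' @param path Input file path.
#' @param modality,tr,rate Metadata attached to the returned object.
#' @return A [region_timeseries].
#' @export
read_timeseries_matrix <- function(path, modality = c("fMRI", "EEG"),
                                   tr = NULL, rate = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop_brainclock("time-series file not found: '%s'", path,
                    class = "brainclock_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) {
    stop_brainclock("'%s' has no data rows", path, class = "brainclock_io_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  labels <- character(length(lines) - 1L)
  vals <- matrix(NA_real_, length(lines) - 1L, width - 1L)
  for (r in seq_along(labels)) {
    row <- fields[[r + 1L]]
    if (length(row) != width) {
      stop_brainclock("ragged row %d in '%s': %d fields, expected %d",
                      r + 1L, path, length(row), width,
                      class = "brainclock_io_error")
    }
    labels[r] <- row[1]
    x <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      stop_brainclock("non-numeric cell at row %d, column %d of '%s': '%s'",
                      r + 1L, bad + 1L, path, row[bad + 1L],
                      class = "brainclock_io_error")
    }
    vals[r, ] <- x
  }
  if (anyDuplicated(labels)) {
    stop_brainclock("duplicate region labels in '%s': %s", path,
                    paste(unique(labels[duplicated(labels)]), collapse = ", "),
                    class = "brainclock_io_error")
  }
  region_timeseries(vals, region_labels = labels, modality = modality,
                    tr = tr, rate = rate)
}

# Generic TSV table writer/reader (header row, full numeric precision).
write_tsv_table <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8"),
    error = function(e) stop_brainclock("cannot write '%s': %s", path,
                                        conditionMessage(e),
                                        class = "brainclock_io_error")
  )
  invisible(path)
}

read_tsv_table <- function(path) {
  if (!file.exists(path)) {
    stop_brainclock("table not found: '%s'", path, class = "brainclock_io_error")
  }
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Write an O-information matrix with sidecar metadata
#'
#' The matrix goes to `<path>` as a square TSV with region labels as header
#' row and first column; normalization constant, modality and sample count go
#' to a JSON sidecar `<path>.json`.
#'
#' @param m An `omega_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_omega_matrix <- function(m, path) {
  stopifnot(inherits(m, "omega_matrix"))
  df <- data.frame(region = m$region_labels, m$omega, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("region", m$region_labels)
  write_tsv_table(df, path)
  jsonlite::write_json(
    list(normalized = m$normalized,
         normalization_constant = m$normalization_constant,
         modality = m$modality, n_samples = m$n_samples),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an O-information matrix written by [write_omega_matrix()]
#' @param path TSV path.
#' @return An `omega_matrix`.
#' @export
read_omega_matrix <- function(path) {
  df <- read_tsv_table(path)
  labels <- as.character(df[[1]])
  om <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(om) <- "double"
  dimnames(om) <- list(labels, labels)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  structure(
    list(omega = om,
         normalized = isTRUE(meta$normalized),
         normalization_constant = meta$normalization_constant %||% NA_real_,
         region_labels = labels,
         modality = meta$modality %||% "fMRI",
         n_samples = meta$n_samples %||% NA_integer_),
    class = "omega_matrix"
  )
}
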