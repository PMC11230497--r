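# Learning-ready brain graphs: adjacency = Omega matrix, node features =
# Omega rows, target = chronological age; plus invalid-case filtering,
# age-stratified splitting, and age-interpolation augmentation
# M_t = (1 - alpha) * M_1 + alpha * M_2 on the training side only.

#' Build a brain graph from an O-information matrix
#'
#' Adjacency is the (normalized) Omega matrix; node i's feature vector is row
#' i of the same matrix; the regression target is the subject's chronological
#' age.
#'
#' @param m An `omega_matrix`.
#' @param record The subject's cohort row (data frame row or named list) with
#'   at least `age`; `subject_id` and grouping columns are carried along.
#' @return An object of class `brain_graph` with fields `adjacency`,
#'   `node_features`, `target_age`, `subject_id`, `meta`, `region_labels`,
#'   `modality`, `is_augmented` (+ `parent_ids`, `alpha` when augmented).
#' @export
build_graph <- function(m, record) {
  stopifnot(inherits(m, "omega_matrix"))
  if (is.data.frame(record)) record <- as.list(record[1, ])
  A <- m$omega
  if (nrow(A) != ncol(A)) {
    stop_brainclock("omega matrix is not square", class = "brainclock_input_error")
  }
  structure(
    list(adjacency = A,
         node_features = A,
         target_age = as.numeric(record$age),
         subject_id = as.character(record$subject_id %||% "subject"),
         meta = record,
         region_labels = m$region_labels,
         modality = m$modality,
         is_augmented = FALSE,
         parent_ids = NULL,
         alpha = NULL),
    class = "brain_graph"
  )
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %s: %d nodes, target age %.1f%s\n",
              x$subject_id, nrow(x$adjacency), x$target_age,
              if (x$is_augmented) " [augmented]" else ""))
  invisible(x)
}

graph_is_finite <- function(g) {
  all(is.finite(g$adjacency)) && all(is.finite(g$node_features)) &&
    length(g$target_age) == 1L && is.finite(g$target_age)
}

#' Drop graphs with non-finite features or targets
#'
#' Removes every graph whose adjacency, feature matrix, or target age
#' contains a NaN/Inf/missing value. Order of the survivors is preserved and
#' the number removed is reported via `message()`.
#'
#' @param graphs List of `brain_graph` objects.
#' @return Filtered list.
#' @export
filter_invalid <- function(graphs) {
  keep <- vapply(graphs, graph_is_finite, logical(1))
  if (any(!keep)) {
    message(sprintf("filter_invalid: removed %d of %d graphs with non-finite values",
                    sum(!keep), length(graphs)))
  }
  graphs[keep]
}

#' Age-stratified train/test split
#'
#' Divides the observed age range into `n_bins` equal-width bins and, within
#' each bin, assigns `round(train_fraction * count)` graphs to the training
#' side after a seeded shuffle. Train and test are disjoint and exhaustive.
#'
#' @param graphs List of `brain_graph` objects (>= `n_bins` recommended).
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param n_bins Number of equal-width age bins; default 5.
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: `train`, `test`, `bin_edges`,
#'   `train_fraction`, `seed`.
#' @export
stratified_split <- function(graphs, train_fraction = 0.8, n_bins = 5, seed = 1L) {
  if (!length(graphs)) {
    stop_brainclock("no graphs to split", class = "brainclock_input_error")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_brainclock("train_fraction must be in (0, 1)", class = "brainclock_input_error")
  }
  ages <- vapply(graphs, function(g) g$target_age, numeric(1))
  edges <- seq(min(ages), max(ages), length.out = n_bins + 1L)
  bin <- findInterval(ages, edges, rightmost.closed = TRUE, all.inside = TRUE)
  train_idx <- integer(0)
  with_seed(seed, {
    for (b in seq_len(n_bins)) {
      members <- which(bin == b)
      if (!length(members)) {
        message(sprintf("stratified_split: age bin %d is empty", b))
        next
      }
      n_train <- round(train_fraction * length(members))
      shuffled <- if (length(members) == 1L) members else sample(members)
      train_idx <- c(train_idx, shuffled[seq_len(n_train)])
    }
  })
  train_idx <- sort(train_idx)
  structure(
    list(train = graphs[train_idx],
         test = graphs[setdiff(seq_along(graphs), train_idx)],
         bin_edges = edges, train_fraction = train_fraction, seed = seed),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (fraction %.2f, %d bins)\n",
              length(x$train), length(x$test), x$train_fraction,
              length(x$bin_edges) - 1L))
  invisible(x)
}

#' Augment training graphs by age interpolation
#'
#' For each new sample, picks an age-adjacent pair of training graphs
#' `(M1, a1), (M2, a2)` (consecutive after sorting by age, ties skipped),
#' draws a target age `a_t` uniformly in `(a1, a2)`, and forms
#' `M_t = (1 - alpha) * M1 + alpha * M2` with `alpha = (a_t - a1)/(a2 - a1)`,
#' applied to the adjacency and feature matrices alike. Augmented graphs are
#' flagged (`is_augmented = TRUE`, with `parent_ids` and `alpha`) and must
#' never enter a test set.
#'
#' @param train List of training `brain_graph` objects (>= 2 distinct ages).
#' @param n_new Number of augmented graphs to create; default 500.
#' @param seed Integer seed.
#' @return List of `n_new` augmented `brain_graph` objects.
#' @export
augment_by_interpolation <- function(train, n_new = 500, seed = 1L) {
  if (length(train) < 2) {
    stop_brainclock("need at least two training graphs", class = "brainclock_input_error")
  }
  ages <- vapply(train, function(g) g$target_age, numeric(1))
  ord <- order(ages)
  # consecutive pairs with a non-degenerate age interval
  lo <- ord[-length(ord)]
  hi <- ord[-1]
  ok <- ages[hi] - ages[lo] > 0
  if (!any(ok)) {
    stop_brainclock("all training ages are equal: no interpolation interval",
                    class = "brainclock_input_error")
  }
  lo <- lo[ok]
  hi <- hi[ok]
  with_seed(seed, {
    pick <- sample.int(length(lo), n_new, replace = TRUE)
    a_t <- runif(n_new, ages[lo[pick]], ages[hi[pick]])
    lapply(seq_len(n_new), function(k) {
      g1 <- train[[lo[pick[k]]]]
      g2 <- train[[hi[pick[k]]]]
      a1 <- g1$target_age
      a2 <- g2$target_age
      alpha <- (a_t[k] - a1) / (a2 - a1)
      M <- (1 - alpha) * g1$adjacency + alpha * g2$adjacency
      g <- g1
      g$adjacency <- M
      g$node_features <- M
      g$target_age <- a_t[k]
      g$subject_id <- sprintf("aug-%04d", k)
      g$meta <- list(subject_id = g$subject_id, age = a_t[k],
                     diagnosis = g1$meta$diagnosis %||% NA_character_)
      g$is_augmented <- TRUE
      g$parent_ids <- c(g1$subject_id, g2$subject_id)
      g$alpha <- alpha
      g
    })
  })
}
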