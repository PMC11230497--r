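# Ablation feature importance with bootstrap confidence intervals.
#
# "Removing" a unit masks it to zero (row+column of the adjacency and of the
# feature matrix for a node; the two symmetric entries for an edge) rather
# than re-indexing, so the trained model's weight shapes are preserved. The
# importance of a unit on one graph is the absolute change in predicted age.

ablate_graph <- function(graph, unit) {
  g <- graph
  if (identical(unit$kind, "node")) {
    k <- unit$index
    if (k < 1 || k > nrow(g$adjacency)) {
      stop_brainclock("node index %d out of range", k, class = "brainclock_input_error")
    }
    g$adjacency[k, ] <- 0
    g$adjacency[, k] <- 0
    g$node_features[k, ] <- 0
    g$node_features[, k] <- 0
  } else if (identical(unit$kind, "edge")) {
    i <- unit$i
    j <- unit$j
    n <- nrow(g$adjacency)
    if (i < 1 || j < 1 || i > n || j > n || i == j) {
      stop_brainclock("edge (%s, %s) out of range", i, j,
                      class = "brainclock_input_error")
    }
    g$adjacency[i, j] <- 0
    g$adjacency[j, i] <- 0
    g$node_features[i, j] <- 0
    g$node_features[j, i] <- 0
  } else {
    stop_brainclock("unit must be a node or an edge", class = "brainclock_input_error")
  }
  g
}

#' Ablate one unit and score the prediction change
#'
#' Computes the model's prediction with the graph intact and with one node or
#' edge masked to zero, and returns the absolute difference in predicted age
#' (years). The input graph is untouched.
#'
#' @param model A `trained_gcn`.
#' @param graph A `brain_graph`.
#' @param unit Either a single node index, or `c(i, j)` for an edge, or a
#'   list `list(kind = "node", index = k)` / `list(kind = "edge", i =, j =)`.
#' @return Absolute prediction delta in years.
#' @export
ablate_and_score <- function(model, graph, unit) {
  stopifnot(inherits(model, "trained_gcn"))
  if (is.numeric(unit)) {
    unit <- if (length(unit) == 1L) {
      list(kind = "node", index = as.integer(unit))
    } else {
      list(kind = "edge", i = as.integer(unit[1]), j = as.integer(unit[2]))
    }
  }
  baseline <- gcn_forward(graph, model$params, training = FALSE)
  ablated <- gcn_forward(ablate_graph(graph, unit), model$params, training = FALSE)
  abs(baseline - ablated)
}

#' Bootstrap ablation importance table
#'
#' Computes every unit's ablation delta on every test graph, then bootstraps
#' the test set (resampling graphs with replacement) to obtain each unit's
#' mean delta and a percentile confidence interval. Edge importance is
#' restricted to the `top_k_edges` edges with the largest mean absolute
#' adjacency weight across the test graphs (configurable to exhaustive).
#'
#' @param model A `trained_gcn`.
#' @param test_graphs Non-empty list of test `brain_graph` objects.
#' @param unit_kind `"node"` or `"edge"`.
#' @param n_bootstrap Bootstrap resamples; default 5000.
#' @param ci Confidence level; default 0.95.
#' @param seed Integer seed.
#' @param top_k_edges Number of edges scored when `unit_kind = "edge"`;
#'   default 200. Use `Inf` for all pairs.
#' @return A `data.frame` of class `importance_table`, sorted by descending
#'   mean delta: `unit`, `mean_delta`, `ci_low`, `ci_high`, `rank`, plus
#'   attributes `n_bootstrap` and `seed`.
#' @export
bootstrap_importance_table <- function(model, test_graphs,
                                       unit_kind = c("node", "edge"),
                                       n_bootstrap = 5000, ci = 0.95,
                                       seed = 1L, top_k_edges = 200) {
  unit_kind <- match.arg(unit_kind)
  if (!length(test_graphs)) {
    stop_brainclock("empty test set", class = "brainclock_input_error")
  }
  if (n_bootstrap < 100) {
    warning("fewer than 100 bootstrap resamples: confidence intervals will be coarse")
  }
  labels <- model$region_labels %||% sprintf("R%03d", seq_len(nrow(test_graphs[[1]]$adjacency)))
  n <- length(labels)
  if (unit_kind == "node") {
    units <- lapply(seq_len(n), function(k) list(kind = "node", index = k))
    unit_names <- labels
  } else {
    W <- Reduce(`+`, lapply(test_graphs, function(g) abs(g$adjacency))) /
      length(test_graphs)
    ut <- which(upper.tri(W), arr.ind = TRUE)
    ord <- order(W[ut], decreasing = TRUE)
    keep <- ord[seq_len(min(top_k_edges, nrow(ut)))]
    units <- lapply(keep, function(r) {
      list(kind = "edge", i = ut[r, 1], j = ut[r, 2])
    })
    unit_names <- vapply(units, function(u) {
      paste0(labels[u$i], "--", labels[u$j])
    }, character(1))
  }
  # per-graph, per-unit deltas computed once
  delta <- matrix(0, length(test_graphs), length(units))
  for (gi in seq_along(test_graphs)) {
    g <- test_graphs[[gi]]
    base <- gcn_forward(g, model$params, training = FALSE)
    for (ui in seq_along(units)) {
      delta[gi, ui] <- abs(base - gcn_forward(ablate_graph(g, units[[ui]]),
                                              model$params, training = FALSE))
    }
  }
  boot_means <- matrix(0, n_bootstrap, length(units))
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(nrow(delta), replace = TRUE)
      boot_means[b, ] <- colMeans(delta[idx, , drop = FALSE])
    }
  })
  alpha <- (1 - ci) / 2
  tab <- data.frame(
    unit = unit_names,
    mean_delta = colMeans(boot_means),
    ci_low = apply(boot_means, 2, quantile, probs = alpha),
    ci_high = apply(boot_means, 2, quantile, probs = 1 - alpha),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$mean_delta, decreasing = TRUE), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "n_bootstrap") <- as.integer(n_bootstrap)
  attr(tab, "seed") <- as.integer(seed)
  attr(tab, "unit_kind") <- unit_kind
  class(tab) <- c("importance_table", "data.frame")
  tab
}
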