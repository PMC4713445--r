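#' Split edges into training and probe sets
#'
#' Uniform random partition of the edge set: a probe fraction (default
#' 10%) is held out as ground truth and the remainder forms the training
#' graph the indices are computed on. The training graph keeps every
#' vertex, so probe removal can disconnect it; scoring handles that via
#' the zero-coordinate convention. No connectivity re-sampling is done.
#'
#' @param g A graph with at least 2 edges.
#' @param fraction Probe proportion in (0, 1); default 0.1.
#' @param seed Optional integer seed for reproducible splits.
#' @return A list of class `linkpred_split`: `train` and `probe` edge
#'   tibbles, `train_graph` (same vertex set as `g`), `graph`, `seed`,
#'   `fraction`. The probe size is `fraction * m` rounded half-up, at
#'   least 1.
#' @examples
#' sp <- split_edges(make_er(20, 0.3, seed = 1), seed = 7)
#' nrow(sp$probe)
#' @export
split_edges <- function(g, fraction = 0.1, seed = NULL) {
  g <- as_linkpred_graph(g)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  edges <- as_edge_tibble(g)
  m <- nrow(edges)
  if (m < 2) stop("need at least 2 edges to split", call. = FALSE)
  n_probe <- max(1L, as.integer(floor(fraction * m + 0.5)))
  if (!is.null(seed)) set.seed(seed)
  probe_idx <- sample.int(m, n_probe)
  train <- edges[-probe_idx, , drop = FALSE]
  probe <- edges[probe_idx, , drop = FALSE]
  vp <- as.vector(t(as.matrix(probe[, c("node_u", "node_v")])))
  tg <- igraph::delete_edges(g, igraph::get_edge_ids(g, vp))
  structure(
    list(train = train, probe = probe, train_graph = tg, graph = g,
         seed = seed, fraction = fraction),
    class = "linkpred_split"
  )
}

# unordered pair key aligned with upper.tri enumeration: (i-1)*n + j, i < j
pair_keys <- function(edges, name_index, n) {
  i <- name_index[edges$node_u]
  j <- name_index[edges$node_v]
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  (lo - 1) * n + hi
}

#' Top-L precision of a scored split
#'
#' Ranks every unordered node pair outside the training edge set by
#' descending score, takes the top `L = |probe|` candidates, and returns
#' the fraction of them that are probe edges. Ties are broken uniformly at
#' random under `seed` — essential for indices whose score mass sits at 0.
#'
#' @param scores A similarity matrix from [similarity_matrix()] or a
#'   `score_tbl` from [similarity_scores()], computed on the training
#'   graph of `split`.
#' @param split A `linkpred_split` from [split_edges()].
#' @param seed Optional integer seed for tie-breaking.
#' @return Precision in `[0, 1]`.
#' @export
precision_at_l <- function(scores, split, seed = NULL) {
  stopifnot(inherits(split, "linkpred_split"))
  if (nrow(split$probe) == 0) stop("empty probe set", call. = FALSE)
  nm <- igraph::V(split$graph)$name
  n <- length(nm)
  name_index <- stats::setNames(seq_len(n), nm)
  if (is.matrix(scores)) {
    ut <- upper.tri(scores)
    ij <- which(ut, arr.ind = TRUE)
    keys <- (ij[, 1] - 1) * n + ij[, 2]
    vals <- scores[ut]
    # matrix rows must align with the graph's vertex order
    stopifnot(identical(rownames(scores), nm))
  } else if (is.data.frame(scores)) {
    keys <- pair_keys(scores, name_index, n)
    vals <- scores$score
  } else {
    stop("scores must be a matrix or a score table", call. = FALSE)
  }
  train_keys <- pair_keys(split$train, name_index, n)
  probe_keys <- pair_keys(split$probe, name_index, n)
  cand <- !(keys %in% train_keys)
  keys <- keys[cand]
  vals <- vals[cand]
  # canonical candidate order so tie-breaking depends only on the seed,
  # not on whether scores arrived as a matrix or a sorted table
  o <- order(keys)
  keys <- keys[o]
  vals <- vals[o]
  L <- nrow(split$probe)
  if (!is.null(seed)) set.seed(seed)
  ord <- order(-vals, stats::runif(length(vals)))
  hits <- sum(keys[ord[seq_len(min(L, length(keys)))]] %in% probe_keys)
  hits / L
}

#' Evaluate a similarity index by iterated train/probe splits
#'
#' Repeats the standard protocol: split the edges, recompute the index
#' on the training graph (the CD-family threshold, when `"diameter"`, is
#' re-resolved on each training graph), rank candidates, score top-L
#' precision, and average over iterations. Iteration `i` uses split seed
#' `seed + i`; the random-score and tie-break streams are seeded at fixed
#' offsets from it so the whole result is reproducible.
#'
#' @param g A graph.
#' @param index Index name (see [index_names()]).
#' @param k CD-family threshold: positive integer or `"diameter"`.
#' @param fraction Probe proportion; default 0.1.
#' @param iterations Number of splits; default 100.
#' @param seed Base seed; default 1.
#' @param ... Passed to [similarity_matrix()].
#' @return A `linkpred_eval` object: tibble of per-iteration results
#'   (`iteration`, `seed`, `precision`, `error`), the mean precision, and
#'   the evaluation settings. Iteration-level scoring failures are kept
#'   and surfaced as a warning, not silently dropped.
#' @examples
#' ev <- evaluate_index(make_er(25, 0.25, seed = 2, connected = TRUE),
#'                      "CN", iterations = 5, seed = 10)
#' glance(ev)
#' @export
evaluate_index <- function(g, index, k = "diameter", fraction = 0.1,
                           iterations = 100, seed = 1, ...) {
  g <- as_linkpred_graph(g)
  stopifnot(iterations >= 1)
  p <- parse_index_name(index, k)
  label <- if (identical(p$k, "diameter") || p$index %in% baseline_names) {
    p$index
  } else {
    paste0(p$index, "-", p$k)
  }
  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    split_seed <- as.integer(seed + it)
    sp <- split_edges(g, fraction, seed = split_seed)
    prec <- NA_real_
    err <- NA_character_
    tryCatch({
      S <- similarity_matrix(sp$train_graph, p$index, k = p$k,
                             seed = split_seed + 250000L, ...)
      prec <- precision_at_l(S, sp, seed = split_seed + 500000L)
    }, error = function(e) err <<- conditionMessage(e))
    rows[[it]] <- tibble::tibble(iteration = it, seed = split_seed,
                                 precision = prec, error = err)
  }
  results <- dplyr::bind_rows(rows)
  n_err <- sum(!is.na(results$error))
  if (n_err > 0) {
    warning(n_err, " iteration(s) failed to score; see $results$error",
            call. = FALSE)
  }
  structure(
    list(index = label, k = p$k, fraction = fraction,
         iterations = iterations, seed = seed, results = results,
         mean_precision = mean(results$precision, na.rm = TRUE)),
    class = "linkpred_eval"
  )
}

#' @export
print.linkpred_eval <- function(x, ...) {
  cat("<linkpred_eval> index:", x$index,
      " iterations:", x$iterations,
      " probe fraction:", x$fraction, "\n")
  cat("  mean precision:", format(x$mean_precision, digits = 4), "\n")
  invisible(x)
}

#' Relative precision against the random predictor
#'
#' @param p Precision of a method (vectorized).
#' @param p_random Precision of the random predictor on the same network.
#' @return `p / p_random`; where `p_random` is 0 the ratio is undefined
#'   and returned as `NA` with a warning.
#' @export
relative_precision <- function(p, p_random) {
  out <- ifelse(p_random > 0, p / p_random, NA_real_)
  if (any(p_random == 0)) {
    warning("relative precision undefined where the random predictor ",
            "scores 0; returned NA", call. = FALSE)
  }
  out
}

#' Mean of a value column by group
#'
#' Convenience aggregation used to average per-network precision within
#' groups (e.g. by assortativity sign).
#'
#' @param data A data frame.
#' @param value Column of values (tidy-eval).
#' @param group Column of group labels (tidy-eval).
#' @return A tibble with one row per group: `group`, `mean_value`, `n`.
#' @export
aggregate_by_group <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(mean_value = mean({{ value }}), n = dplyr::n(),
                     .groups = "drop")
}

#' Topology summary of a network
#'
#' The standard descriptive metrics for a benchmark network: size,
#' efficiency (mean inverse shortest-path length over unordered pairs,
#' with `1/Inf := 0`), clustering coefficient, degree assortativity,
#' degree heterogeneity \eqn{\langle k^2\rangle/\langle k\rangle^2}, and
#' diameter.
#'
#' @param g A graph with at least 2 nodes.
#' @param clustering `"average"` (mean local clustering, isolated and
#'   degree-1 nodes counting 0; the default) or `"global"` (transitivity
#'   ratio).
#' @return A one-row tibble: `n`, `m`, `efficiency`, `clustering`,
#'   `assortativity`, `heterogeneity`, `diameter`, `connected`.
#' @examples
#' topology_summary(make_toy("path", 3))
#' @export
topology_summary <- function(g, clustering = c("average", "global")) {
  g <- as_linkpred_graph(g)
  clustering <- match.arg(clustering)
  n <- igraph::vcount(g)
  if (n < 2) stop("topology summary needs at least 2 nodes", call. = FALSE)
  D <- shortest_path_matrix(g)
  inv <- 1 / D[upper.tri(D)]
  eff <- 2 / (n * (n - 1)) * sum(inv)
  cc <- if (clustering == "average") {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  } else {
    igraph::transitivity(g, type = "global")
  }
  deg <- igraph::degree(g)
  dm <- graph_diameter(D)
  tibble::tibble(
    n = n,
    m = igraph::ecount(g),
    efficiency = eff,
    clustering = cc,
    assortativity = igraph::assortativity_degree(g),
    heterogeneity = mean(deg^2) / mean(deg)^2,
    diameter = as.integer(dm),
    connected = !attr(dm, "disconnected")
  )
}
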