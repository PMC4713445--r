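#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-iteration results of an index evaluation
#'
#' @param x A `linkpred_eval` from [evaluate_index()].
#' @param ... Unused.
#' @return A tibble with one row per iteration: `index`, `iteration`,
#'   `seed`, `precision`, `error`.
#' @export
tidy.linkpred_eval <- function(x, ...) {
  dplyr::mutate(x$results, index = x$index, .before = 1)
}

#' One-row summary of an index evaluation
#'
#' @param x A `linkpred_eval` from [evaluate_index()].
#' @param ... Unused.
#' @return A one-row tibble: `index`, `iterations`, `fraction`,
#'   `mean_precision`, `sd_precision`, `se_precision`, `n_failed`.
#' @export
glance.linkpred_eval <- function(x, ...) {
  p <- x$results$precision
  ok <- sum(!is.na(p))
  tibble::tibble(
    index = x$index,
    iterations = x$iterations,
    fraction = x$fraction,
    mean_precision = x$mean_precision,
    sd_precision = stats::sd(p, na.rm = TRUE),
    se_precision = stats::sd(p, na.rm = TRUE) / sqrt(ok),
    n_failed = sum(!is.na(x$results$error))
  )
}

#' Plot per-iteration precision of an evaluation
#'
#' @param object A `linkpred_eval` from [evaluate_index()].
#' @param ... Unused.
#' @return A ggplot: precision per iteration with the mean as a line.
#' @export
autoplot.linkpred_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$precision)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_precision,
                        linetype = "dashed") +
    ggplot2::labs(
      title = paste0(object$index, ": precision over ", object$iterations,
                     " splits"),
      subtitle = sprintf("mean precision %.4f", object$mean_precision),
      x = "iteration", y = "precision"
    )
}

#' Plot the score distribution of a score table
#'
#' @param object A `score_tbl` from [similarity_scores()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot histogram of pair scores.
#' @export
autoplot.score_tbl <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(title = paste0(object$index[1], " score distribution"),
                  x = "score", y = "pairs")
}

#' Compare several indices on one network
#'
#' Convenience wrapper running [evaluate_index()] for each requested index
#' under a shared base seed (so all indices see identical splits) and
#' binding the one-row summaries.
#'
#' @param g A graph.
#' @param indices Character vector of index names.
#' @param ... Passed to [evaluate_index()] (e.g. `iterations`, `seed`,
#'   `k`).
#' @return A tibble with one [glance()] row per index.
#' @export
compare_indices <- function(g, indices, ...) {
  g <- as_linkpred_graph(g)
  purrr::map_dfr(indices, function(ix) glance(evaluate_index(g, ix, ...)))
}
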