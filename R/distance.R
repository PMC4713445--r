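#' All-pairs shortest paths by frontier expansion
#'
#' Computes the hop-count distance matrix of an unweighted undirected graph
#' with a per-source breadth-first frontier expansion: starting from the
#' source's neighbors at distance 1, the nodes at distance `k` are located,
#' the union of their not-yet-visited neighbors is stamped `k + 1`, and the
#' sweep repeats until the frontier empties. Unreachable pairs keep the
#' `Inf` sentinel, which downstream coordinate construction maps to 0.
#'
#' @param g A graph (anything [as_linkpred_graph()] accepts).
#' @return A symmetric numeric matrix of shortest-path lengths with zero
#'   diagonal, `Inf` for unreachable pairs, and vertex names on both
#'   dimensions.
#' @examples
#' shortest_path_matrix(make_toy("path", 3))
#' @export
shortest_path_matrix <- function(g) {
  g <- as_linkpred_graph(g)
  n <- igraph::vcount(g)
  if (n < 1) stop("empty graph", call. = FALSE)
  adj <- adjacency_lists(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) {
    frontier <- adj[[i]]
    k <- 1
    while (length(frontier)) {
      D[i, frontier] <- k
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      frontier <- nxt[is.infinite(D[i, nxt])]
      k <- k + 1
    }
  }
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

#' Threshold a distance matrix at k
#'
#' Entries exceeding the threshold are replaced by `Inf`; entries at or
#' below it pass through, as does the zero diagonal. With `k` equal to the
#' diameter the result equals the distance matrix itself.
#'
#' @param d A distance matrix from [shortest_path_matrix()].
#' @param k Positive integer threshold.
#' @return The thresholded matrix, with the threshold recorded in
#'   attribute `"k"`.
#' @export
k_distance_matrix <- function(d, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("threshold k must be a positive integer", call. = FALSE)
  }
  L <- d
  L[d > k] <- Inf
  diag(L) <- 0
  attr(L, "k") <- as.integer(k)
  L
}

#' Node coordinate matrix
#'
#' Inverts a (thresholded) distance matrix entrywise, with `1/Inf := 0` for
#' pairs beyond the threshold or in different components, and sets the
#' diagonal to exactly 1 so that every row is a nonzero coordinate vector.
#' With threshold 1 the result is `A + I`.
#'
#' @param l A matrix from [k_distance_matrix()] (or a plain distance
#'   matrix).
#' @return A symmetric matrix with unit diagonal and off-diagonal entries
#'   that are 0 or reciprocals of integers; row `i` is the coordinate of
#'   node `i`.
#' @export
coordinate_matrix <- function(l) {
  C <- 1 / l
  C[is.infinite(l)] <- 0
  diag(C) <- 1
  attr(C, "k") <- attr(l, "k")
  C
}

#' Graph diameter from a distance matrix
#'
#' The maximum finite off-diagonal shortest-path length. For a disconnected
#' graph the `Inf` entries are ignored and the finite diameter is returned,
#' flagged by attribute `"disconnected"`.
#'
#' @param d A distance matrix, or a graph (converted via
#'   [shortest_path_matrix()]).
#' @return Integer diameter, with logical attribute `"disconnected"`.
#' @export
graph_diameter <- function(d) {
  if (igraph::is_igraph(d) || is.data.frame(d)) {
    d <- shortest_path_matrix(d)
  }
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (!length(fin)) {
    stop("diameter undefined: no finite off-diagonal distances",
         call. = FALSE)
  }
  structure(as.integer(max(fin)), disconnected = any(is.infinite(off)))
}
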