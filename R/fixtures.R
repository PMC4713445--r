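#' Deterministic toy graphs
#'
#' Canonical small graphs used throughout the test suite and examples.
#'
#' @param family `"path"`, `"cycle"`, `"star"` or `"complete"`.
#' @param n Size: node count for path/cycle/complete, leaf count for star
#'   (the star has `n + 1` nodes with the center first).
#' @return An igraph object with character vertex names `"1"`, `"2"`, ...
#' @examples
#' igraph::ecount(make_toy("complete", 4))
#' @export
make_toy <- function(family = c("path", "cycle", "star", "complete"), n) {
  family <- match.arg(family)
  g <- switch(family,
    path = igraph::make_ring(n, circular = FALSE),
    cycle = igraph::make_ring(n, circular = TRUE),
    star = igraph::make_star(n + 1, mode = "undirected", center = 1),
    complete = igraph::make_full_graph(n)
  )
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Erdos-Renyi random graph
#'
#' @param n Node count.
#' @param p Edge probability.
#' @param seed Optional seed.
#' @param connected If `TRUE`, resample (from the same seeded stream)
#'   until the graph is connected.
#' @return A named igraph object.
#' @export
make_er <- function(n, p, seed = NULL, connected = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (!connected || igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Grows from `m_attach` initially edgeless seed nodes: each arriving node
#' links to `m_attach` distinct existing nodes chosen with probability
#' proportional to degree (uniformly while all degrees are zero, so the
#' first arrival wires up the whole seed). The result is connected with
#' exactly `m_attach * (n - m_attach)` edges.
#'
#' @param n Final node count (`n > m_attach`).
#' @param m_attach Edges added per arriving node.
#' @param seed Optional seed.
#' @return A named igraph object.
#' @examples
#' igraph::ecount(make_ba(100, 2, seed = 1))  # 196
#' @export
make_ba <- function(n, m_attach, seed = NULL) {
  stopifnot(n > m_attach, m_attach >= 1)
  if (!is.null(seed)) set.seed(seed)
  deg <- numeric(n)
  from <- integer(0)
  to <- integer(0)
  for (t in seq(m_attach + 1, n)) {
    existing <- seq_len(t - 1)
    targets <- if (sum(deg[existing]) == 0) {
      existing[sample.int(length(existing), m_attach)]
    } else {
      existing[sample.int(length(existing), m_attach,
                          prob = deg[existing])]
    }
    from <- c(from, rep.int(t, length(targets)))
    to <- c(to, targets)
    deg[targets] <- deg[targets] + 1
    deg[t] <- deg[t] + length(targets)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Watts-Strogatz small-world graph
#'
#' @param n Node count.
#' @param nei Neighborhood radius of the starting ring lattice.
#' @param p Rewiring probability.
#' @param seed Optional seed.
#' @return A connected, simple, named igraph object (resampled from the
#'   seeded stream until connected).
#' @export
make_ws <- function(n, nei = 2, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    g <- igraph::simplify(igraph::sample_smallworld(1, n, nei, p))
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Add a structurally equivalent twin of a node
#'
#' Appends one node whose neighbor set is exactly that of `node` (and no
#' edge between twin and original), producing a pair of structurally
#' equivalent nodes: their CD scores against any third node coincide.
#'
#' @param base A graph.
#' @param node Vertex name or index to twin.
#' @return The augmented graph; the twin is the last vertex, named
#'   `"<node>_twin"`.
#' @export
make_struct_equiv <- function(base, node) {
  g <- as_linkpred_graph(base)
  v <- igraph::V(g)[[node]]
  nbrs <- as.integer(igraph::neighbors(g, v))
  twin_name <- paste0(igraph::V(g)$name[v], "_twin")
  g2 <- igraph::add_vertices(g, 1, name = twin_name)
  tw <- igraph::vcount(g2)
  if (length(nbrs)) {
    g2 <- igraph::add_edges(g2, rbind(tw, nbrs))
  }
  g2
}
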