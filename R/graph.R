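#' Coerce to a simple undirected link-prediction graph
#'
#' All scoring and evaluation functions in cdlink operate on a simple
#' (no self-loops, no multi-edges), undirected, unweighted graph whose
#' vertices carry character names. `as_linkpred_graph()` accepts either an
#' [igraph::igraph] object or a data frame whose first two columns are the
#' endpoints of each edge, and returns a validated igraph object. Vertex
#' order is preserved (for data frames, first-appearance order), and every
#' matrix produced downstream is indexed in that order.
#'
#' @param x An igraph object or a data frame / tibble with at least two
#'   columns giving edge endpoints. Additional columns are ignored.
#' @return An undirected simple igraph object with named vertices.
#' @examples
#' g <- as_linkpred_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::vcount(g)
#' @export
as_linkpred_graph <- function(x) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) {
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
      g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    }
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    return(g)
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      stop("edge data frame needs at least two columns", call. = FALSE)
    }
    u <- as.character(x[[1]])
    v <- as.character(x[[2]])
    return(graph_from_edges(u, v, warn_loops = FALSE))
  }
  stop("cannot interpret object of class '", class(x)[1],
       "' as a graph", call. = FALSE)
}

# Build a simple undirected graph from endpoint vectors; node order is
# first-appearance order over the interleaved endpoint sequence.
graph_from_edges <- function(u, v, warn_loops = TRUE) {
  loops <- u == v
  if (any(loops) && warn_loops) {
    warning(sum(loops), " self-loop line(s) dropped", call. = FALSE)
  }
  nodes <- unique(as.vector(rbind(u, v)))
  u <- u[!loops]
  v <- v[!loops]
  # nodes seen only in self-loop lines are isolated; drop them entirely
  nodes <- nodes[nodes %in% c(u, v)]
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(u)) {
    ii <- match(u, nodes)
    jj <- match(v, nodes)
    g <- igraph::add_edges(g, rbind(ii, jj))
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read an edge list file
#'
#' Reads a plain-text edge list: one edge per line, two whitespace- or
#' tab-separated node identifiers, lines starting with `#` ignored.
#' Repeated lines and reversed duplicates collapse to a single undirected
#' edge; self-loop lines are dropped with a warning. Node order is
#' first-appearance order in the file.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param delimiter Optional delimiter; by default any run of whitespace.
#' @return An undirected simple igraph object with named vertices.
#' @examples
#' g <- read_edge_list(c("a b", "b c", "# comment"))
#' igraph::ecount(g)
#' @export
read_edge_list <- function(source, delimiter = NULL) {
  lines <- if (length(source) == 1 && !grepl("\n", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- if (is.null(delimiter)) {
    strsplit(trimws(lines[keep]), "\\s+")
  } else {
    strsplit(trimws(lines[keep]), delimiter, fixed = TRUE)
  }
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge list: fewer than 2 tokens on line ", idx[bad[1]],
         call. = FALSE)
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  graph_from_edges(u, v)
}

#' Write a canonical edge list
#'
#' Emits one edge per line with endpoints in lexicographic order within a
#' line and lines sorted, so that two graphs with the same edge set always
#' serialize identically.
#'
#' @param g A graph (anything [as_linkpred_graph()] accepts).
#' @param path File path to write to; with `path = NULL` the lines are
#'   returned invisibly instead.
#' @return Invisibly, the character vector of lines.
#' @export
write_edge_list <- function(g, path = NULL) {
  g <- as_linkpred_graph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    tmp <- el[swap, 1]
    el[swap, 1] <- el[swap, 2]
    el[swap, 2] <- tmp
  }
  lines <- sort(paste(el[, 1], el[, 2], sep = "\t"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Edges of a graph as a tibble
#'
#' @param g A graph (anything [as_linkpred_graph()] accepts).
#' @return A tibble with character columns `node_u`, `node_v`; within each
#'   row `node_u` precedes `node_v` in vertex order.
#' @export
as_edge_tibble <- function(g) {
  g <- as_linkpred_graph(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  nm <- igraph::V(g)$name
  i <- pmin(el[, 1], el[, 2])
  j <- pmax(el[, 1], el[, 2])
  tibble::tibble(node_u = nm[i], node_v = nm[j])
}

#' Degree of one node
#'
#' Thin wrapper over [igraph::degree()] for a single, named or indexed,
#' vertex.
#'
#' @param g A graph.
#' @param v A vertex name or index.
#' @return Integer neighbor count.
#' @export
node_degree <- function(g, v) {
  g <- as_linkpred_graph(g)
  unname(igraph::degree(g, v))
}

#' Common neighbors of a node pair
#'
#' @param g A graph.
#' @param i,j Distinct vertex names or indices.
#' @return Character vector of the names of the shared neighbors
#'   \eqn{\Gamma(i) \cap \Gamma(j)} (never containing `i` or `j`).
#' @export
common_neighbors <- function(g, i, j) {
  g <- as_linkpred_graph(g)
  vi <- igraph::V(g)[[i]]
  vj <- igraph::V(g)[[j]]
  if (vi == vj) stop("common_neighbors() needs two distinct nodes",
                     call. = FALSE)
  ni <- igraph::neighbors(g, vi)$name
  nj <- igraph::neighbors(g, vj)$name
  setdiff(intersect(ni, nj), c(igraph::V(g)$name[c(vi, vj)]))
}

#' Is the graph connected?
#'
#' @param g A non-empty graph.
#' @return `TRUE` iff every node is reachable from the first node.
#' @export
is_connected_graph <- function(g) {
  g <- as_linkpred_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  igraph::is_connected(g)
}

# dense 0/1 adjacency matrix with vertex names on both dimensions
adjacency_dense <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  storage.mode(A) <- "double"
  A
}

# neighbor index lists (integer), one per vertex
adjacency_lists <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}
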