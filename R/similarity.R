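#' Cosine similarity of two coordinate vectors
#'
#' The cosine of the angle between two node coordinates: their dot product
#' divided by the product of their Euclidean norms. This is the kernel of
#' the CD index.
#'
#' @param x,y Numeric vectors of equal length, not both zero.
#' @return The cosine, in `[-1, 1]` (in `[0, 1]` for nonnegative inputs).
#' @examples
#' cosine_similarity(c(1, 0.2, 0.4), c(0.2, 1, 0.5))
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm coordinate vector", call. = FALSE)
  sum(x * y) / (nx * ny)
}

# canonical index roster
cd_family_names <- c("CD", "CD-LD", "CD*LD", "CDI")
baseline_names <- c("CN", "Salton", "Sorensen", "LHN", "PA", "RA",
                    "LP3", "LP4", "LRW", "CAR", "CPA", "CAA", "CRA",
                    "CJC", "RANDOM")

#' Implemented similarity indices
#'
#' @return Character vector of the index names accepted by
#'   [similarity_matrix()] and [similarity_scores()]. Suffixed spellings
#'   such as `"CD-LD-3"` select the same index at threshold `k = 3`.
#' @export
index_names <- function() c(cd_family_names, baseline_names)

# "CD-3" / "CD-LD-2" / "CD*LD-4" -> list(base, k); others pass through
parse_index_name <- function(index, k) {
  m <- regmatches(index, regexec("^(CD|CD-LD|CD\\*LD)-([0-9]+)$", index))[[1]]
  if (length(m)) {
    return(list(index = m[2], k = as.integer(m[3])))
  }
  norm <- c(`LP-3` = "LP3", `LP-4` = "LP4")
  if (index %in% names(norm)) index <- norm[[index]]
  if (!index %in% index_names()) {
    stop("unknown similarity index '", index, "'", call. = FALSE)
  }
  list(index = index, k = k)
}

resolve_k <- function(k, dmax) {
  if (identical(k, "diameter")) return(as.integer(dmax))
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop("k must be a positive integer or \"diameter\"", call. = FALSE)
  }
  k <- as.integer(k)
  if (k > dmax) {
    message("threshold k = ", k, " exceeds diameter ", dmax,
            "; clamped (equivalent result)")
    k <- as.integer(dmax)
  }
  k
}

# cosine similarity between all rows of a symmetric coordinate matrix
cosine_rows <- function(C) {
  M <- C %*% C
  nrm <- sqrt(diag(M))
  S <- M / tcrossprod(nrm)
  pmin(pmax(S, 0), 1)
}

#' CD similarity matrix
#'
#' Cosine similarity between the coordinate vectors of every node pair.
#' Coordinates are rows of the inverse thresholded distance matrix
#' ([coordinate_matrix()]); the threshold defaults to the graph diameter.
#'
#' @param g A graph (anything [as_linkpred_graph()] accepts).
#' @param k Positive integer threshold, or `"diameter"` (the default).
#'   Values above the diameter are clamped with a message.
#' @return Symmetric numeric matrix of CD scores in `[0, 1]` with unit
#'   diagonal; attribute `"k"` records the threshold used.
#' @export
cd_matrix <- function(g, k = "diameter") {
  g <- as_linkpred_graph(g)
  D <- shortest_path_matrix(g)
  dmax <- graph_diameter(D)
  kk <- resolve_k(k, dmax)
  S <- cosine_rows(coordinate_matrix(k_distance_matrix(D, kk)))
  attr(S, "k") <- kk
  attr(S, "diameter") <- as.integer(dmax)
  S
}

#' CD score of a single node pair
#'
#' @param c_mat A coordinate matrix from [coordinate_matrix()].
#' @param i,j Distinct row indices or names.
#' @return Cosine similarity of rows `i` and `j`, in `[0, 1]`.
#' @export
cd_score <- function(c_mat, i, j) {
  if (is.character(i)) i <- match(i, rownames(c_mat))
  if (is.character(j)) j <- match(j, rownames(c_mat))
  if (is.na(i) || is.na(j) || i == j) {
    stop("cd_score() needs two distinct valid nodes", call. = FALSE)
  }
  min(max(cosine_similarity(c_mat[i, ], c_mat[j, ]), 0), 1)
}

#' Local-community-density (LD) matrix for a base index
#'
#' For each node pair, sums the base similarity over the unordered distinct
#' pairs of their common neighbors: the denser (under the base index) the
#' local community shared by the two nodes, the larger the score. Pairs
#' with fewer than two common neighbors score 0 (or, with
#' `include_self = TRUE`, pairs with no common neighbor).
#'
#' @param g A graph.
#' @param base Symmetric base-score matrix aligned with `g`'s vertices
#'   (e.g. a [cd_matrix()]).
#' @param include_self If `TRUE`, the degenerate `p = q` terms (the base
#'   matrix diagonal) are added once per common neighbor. Default `FALSE`:
#'   distinct pairs only.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
ld_matrix <- function(g, base, include_self = FALSE) {
  g <- as_linkpred_graph(g)
  n <- igraph::vcount(g)
  stopifnot(nrow(base) == n, ncol(base) == n)
  A <- adjacency_dense(g)
  adj <- adjacency_lists(g)
  CN <- A %*% A
  thr <- if (include_self) 1 else 2
  L <- matrix(0, n, n, dimnames = dimnames(A))
  dB <- diag(base)
  pr <- which(upper.tri(CN) & CN >= thr, arr.ind = TRUE)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]
    j <- pr[r, 2]
    cn <- intersect(adj[[i]], adj[[j]])
    val <- (sum(base[cn, cn]) - sum(dB[cn])) / 2
    if (include_self) val <- val + sum(dB[cn])
    L[i, j] <- L[j, i] <- val
  }
  L
}

# external degree of each endpoint w.r.t. a pair: k_x - CN_ij - a_ij
car_family_matrices <- function(g) {
  A <- adjacency_dense(g)
  adj <- adjacency_lists(g)
  n <- nrow(A)
  deg <- rowSums(A)
  CN <- A %*% A
  diag(CN) <- 0
  CAR <- CAA <- CRA <- matrix(0, n, n, dimnames = dimnames(A))
  pr <- which(upper.tri(CN) & CN >= 1, arr.ind = TRUE)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1]
    j <- pr[r, 2]
    cn <- intersect(adj[[i]], adj[[j]])
    gz <- rowSums(A[cn, cn, drop = FALSE])  # links of each z to other CNs
    lcl <- sum(gz) / 2
    CAR[i, j] <- CAR[j, i] <- CN[i, j] * lcl
    CAA[i, j] <- CAA[j, i] <- sum(gz / log2(deg[cn]))
    CRA[i, j] <- CRA[j, i] <- sum(gz / deg[cn])
  }
  EI <- matrix(deg, n, n) - CN - A  # e_i as a function of the pair (i,j)
  CPA <- EI * t(EI) + (EI + t(EI)) * CAR + CAR^2
  diag(CPA) <- 0
  UNION <- outer(deg, deg, "+") - CN
  CJC <- ifelse(UNION > 0, CAR / UNION, 0)
  diag(CJC) <- 0
  list(CAR = CAR, CPA = CPA, CAA = CAA, CRA = CRA, CJC = CJC)
}

baseline_matrix <- function(g, index, eps = 0.01, lrw_steps = 3,
                            seed = NULL) {
  g <- as_linkpred_graph(g)
  A <- adjacency_dense(g)
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(deg) / 2
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  CN <- A %*% A
  diag(CN) <- 0
  S <- switch(index,
    CN = CN,
    Salton = safe_div(CN, sqrt(outer(deg, deg))),
    Sorensen = safe_div(2 * CN, outer(deg, deg, "+")),
    LHN = safe_div(CN, outer(deg, deg)),
    PA = {
      P <- outer(deg, deg)
      diag(P) <- 0
      P
    },
    RA = {
      w <- ifelse(deg > 0, 1 / deg, 0)
      R <- A %*% (w * A)
      diag(R) <- 0
      R
    },
    LP3 = ,
    LP4 = {
      A2 <- A %*% A
      A3 <- A2 %*% A
      P <- A2 + eps * A3
      if (index == "LP4") P <- P + eps^2 * (A3 %*% A)
      diag(P) <- 0
      P
    },
    LRW = {
      P <- ifelse(deg > 0, 1 / deg, 0) * A  # row-stochastic transition
      Pt <- P
      t <- 1
      while (t < lrw_steps) {
        Pt <- Pt %*% P
        t <- t + 1
      }
      Q <- (deg / (2 * m)) * Pt  # q_i * pi_ij(t), rows scaled
      R <- Q + t(Q)
      diag(R) <- 0
      R
    },
    CAR = ,
    CPA = ,
    CAA = ,
    CRA = ,
    CJC = car_family_matrices(g)[[index]],
    RANDOM = {
      if (!is.null(seed)) set.seed(seed)
      R <- matrix(0, n, n, dimnames = dimnames(A))
      R[upper.tri(R)] <- stats::runif(n * (n - 1) / 2)
      R + t(R)
    },
    stop("unknown baseline index '", index, "'", call. = FALSE)
  )
  dimnames(S) <- dimnames(A)
  S
}

#' Similarity matrix for any implemented index
#'
#' Single entry point dispatching to the CD family (`"CD"`, `"CD-LD"`,
#' `"CD*LD"`, `"CDI"`, with threshold `k`) and the fourteen classical
#' baselines plus the `"RANDOM"` predictor. Suffixed names (`"CD-3"`,
#' `"CD-LD-2"`, ...) select the threshold directly.
#'
#' @param g A graph (anything [as_linkpred_graph()] accepts).
#' @param index Index name; see [index_names()].
#' @param k Threshold for the CD family: positive integer or `"diameter"`.
#' @param eps Local-path damping parameter for LP3/LP4 (default 0.01).
#' @param lrw_steps Local random walk length (default 3).
#' @param seed Seed for the `"RANDOM"` predictor's scores.
#' @param include_self Passed to [ld_matrix()] for the LD-based indices.
#' @return Symmetric score matrix with vertex names; attributes `"index"`
#'   (resolved label, e.g. `"CD-LD-3"`) and, for the CD family, `"k"`.
#' @export
similarity_matrix <- function(g, index, k = "diameter", eps = 0.01,
                              lrw_steps = 3, seed = NULL,
                              include_self = FALSE) {
  g <- as_linkpred_graph(g)
  p <- parse_index_name(index, k)
  index <- p$index
  k <- p$k
  if (index %in% baseline_names) {
    S <- baseline_matrix(g, index, eps = eps, lrw_steps = lrw_steps,
                         seed = seed)
    attr(S, "index") <- index
    return(S)
  }
  CD <- cd_matrix(g, k)
  kk <- attr(CD, "k")
  dmax <- attr(CD, "diameter")
  lab <- function(base) {
    if (identical(k, "diameter") || kk == dmax) base else paste0(base, "-", kk)
  }
  S <- switch(index,
    CD = CD,
    `CD-LD` = ld_matrix(g, CD, include_self = include_self),
    `CD*LD` = CD * ld_matrix(g, CD, include_self = include_self),
    CDI = {
      deg <- igraph::degree(g)
      CD * outer(deg, deg)
    }
  )
  if (index == "CD*LD") diag(S) <- 0
  attr(S, "index") <- lab(index)
  attr(S, "k") <- kk
  S
}

#' Tidy table of similarity scores
#'
#' Computes [similarity_matrix()] and melts it to one row per unordered
#' node pair, sorted by descending score.
#'
#' @inheritParams similarity_matrix
#' @param ... Passed on to [similarity_matrix()].
#' @return A tibble of class `score_tbl` with columns `index`, `node_u`,
#'   `node_v`, `score`; self-pairs are excluded and each unordered pair
#'   appears once (`node_u` before `node_v` in vertex order).
#' @examples
#' similarity_scores(make_toy("path", 4), "CN")
#' @export
similarity_scores <- function(g, index, ...) {
  g <- as_linkpred_graph(g)
  S <- similarity_matrix(g, index, ...)
  nm <- rownames(S)
  ut <- which(upper.tri(S), arr.ind = TRUE)
  out <- tibble::tibble(
    index = attr(S, "index"),
    node_u = nm[ut[, 1]],
    node_v = nm[ut[, 2]],
    score = S[ut]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$score))
  class(out) <- c("score_tbl", class(out))
  attr(out, "k") <- attr(S, "k")
  out
}

#' Write a score table as TSV
#'
#' @param scores A `score_tbl` from [similarity_scores()].
#' @param path Output path.
#' @return Invisibly, `scores`.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(scores)
}
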