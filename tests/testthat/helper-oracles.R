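# Independent reference implementations used as oracles. Deliberately
# written as plain loops over the defining formulas (no shared code with
# the package's matrix-algebra paths), tractable for n <= ~40.

adjacency_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  storage.mode(A) <- "double"
  A
}

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (h in seq_len(n)) {
    D <- pmin(D, outer(D[, h], D[h, ], "+"))
  }
  dimnames(D) <- dimnames(A)
  D
}

oracle_cd_matrix <- function(g, k = NULL) {
  A <- adjacency_of(g)
  D <- floyd_warshall(A)
  n <- nrow(A)
  off <- D[row(D) != col(D)]
  if (is.null(k)) k <- max(off[is.finite(off)])
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- if (i == j) 1 else if (D[i, j] <= k) 1 / D[i, j] else 0
    }
  }
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dot <- ni <- nj <- 0
      for (x in seq_len(n)) {
        dot <- dot + C[i, x] * C[j, x]
        ni <- ni + C[i, x]^2
        nj <- nj + C[j, x]^2
      }
      S[i, j] <- dot / sqrt(ni * nj)
    }
  }
  S
}

oracle_ld_matrix <- function(g, base, include_self = FALSE) {
  A <- adjacency_of(g)
  n <- nrow(A)
  L <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cn <- which(A[i, ] == 1 & A[j, ] == 1)
      s <- 0
      for (pi in seq_along(cn)) {
        for (qi in seq_along(cn)) {
          if (pi < qi) s <- s + base[cn[pi], cn[qi]]
          if (include_self && pi == qi) s <- s + base[cn[pi], cn[pi]]
        }
      }
      L[i, j] <- s
    }
  }
  L
}

# three-step transition probability by explicit walk enumeration
oracle_walk_prob <- function(A, i, j, steps) {
  n <- nrow(A)
  deg <- unname(rowSums(A))
  P <- function(a, b) if (deg[a] > 0) A[a, b] / deg[a] else 0
  if (steps == 1) return(P(i, j))
  if (steps == 2) {
    s <- 0
    for (x in seq_len(n)) s <- s + P(i, x) * P(x, j)
    return(s)
  }
  s <- 0
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      s <- s + P(i, x) * P(x, y) * P(y, j)
    }
  }
  s
}

oracle_baseline_matrix <- function(g, index, eps = 0.01, lrw_steps = 3) {
  A <- adjacency_of(g)
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(deg) / 2
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cn <- which(A[i, ] == 1 & A[j, ] == 1)
      ncn <- length(cn)
      S[i, j] <- switch(index,
        CN = ncn,
        Salton = if (deg[i] * deg[j] > 0) ncn / sqrt(deg[i] * deg[j]) else 0,
        Sorensen = if (deg[i] + deg[j] > 0) 2 * ncn / (deg[i] + deg[j]) else 0,
        LHN = if (deg[i] * deg[j] > 0) ncn / (deg[i] * deg[j]) else 0,
        PA = deg[i] * deg[j],
        RA = sum(1 / deg[cn]),
        LP3 = ,
        LP4 = {
          p2 <- 0
          for (x in seq_len(n)) p2 <- p2 + A[i, x] * A[x, j]
          p3 <- 0
          for (x in seq_len(n)) for (y in seq_len(n)) {
            p3 <- p3 + A[i, x] * A[x, y] * A[y, j]
          }
          v <- p2 + eps * p3
          if (index == "LP4") {
            p4 <- 0
            for (x in seq_len(n)) for (y in seq_len(n)) for (z in seq_len(n)) {
              p4 <- p4 + A[i, x] * A[x, y] * A[y, z] * A[z, j]
            }
            v <- v + eps^2 * p4
          }
          v
        },
        LRW = {
          q <- deg / (2 * m)
          q[i] * oracle_walk_prob(A, i, j, lrw_steps) +
            q[j] * oracle_walk_prob(A, j, i, lrw_steps)
        },
        CAR = ,
        CPA = ,
        CAA = ,
        CRA = ,
        CJC = {
          lcl <- 0
          for (pi in seq_along(cn)) for (qi in seq_along(cn)) {
            if (pi < qi) lcl <- lcl + A[cn[pi], cn[qi]]
          }
          car <- ncn * lcl
          switch(index,
            CAR = car,
            CPA = {
              ei <- deg[i] - ncn - A[i, j]
              ej <- deg[j] - ncn - A[i, j]
              ei * ej + ei * car + ej * car + car^2
            },
            CAA = {
              s <- 0
              for (z in cn) s <- s + sum(A[z, cn]) / log2(deg[z])
              s
            },
            CRA = {
              s <- 0
              for (z in cn) s <- s + sum(A[z, cn]) / deg[z]
              s
            },
            CJC = {
              un <- length(which(A[i, ] == 1 | A[j, ] == 1))
              if (un > 0) car / un else 0
            }
          )
        },
        stop("no oracle for ", index)
      )
    }
  }
  S
}
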