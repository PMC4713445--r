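test_that("cosine kernel reproduces hand-checked coordinate examples", {
  # dot/norm arithmetic frozen by hand: (0.2+0.2+0.2)/sqrt(1.2*1.29)
  expect_equal(cosine_similarity(c(1, 0.2, 0.4), c(0.2, 1, 0.5)),
               0.6 / sqrt(1.2 * 1.29), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(0, 0.2, 0.4), c(0.2, 0, 0.5)),
               0.2 / sqrt(0.2 * 0.29), tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 2, 3), c(2, 4, 6)), 1, tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
})

test_that("cd_score works on coordinate rows and rejects self-pairs", {
  g <- make_toy("path", 3)
  C <- coordinate_matrix(shortest_path_matrix(g))
  expect_equal(cd_score(C, "1", "3"), cd_score(C, "3", "1"))
  expect_error(cd_score(C, "2", "2"), "distinct")
  S <- cd_matrix(g)
  expect_equal(S["1", "3"], cd_score(C, 1, 3), tolerance = 1e-12)
})

test_that("CD matrix equals the brute-force cosine oracle", {
  for (g in small_fixtures()) {
    S <- cd_matrix(g)
    expect_equal(unname(S), unname(oracle_cd_matrix(g)),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # and at every smaller threshold
    dmax <- as.integer(attr(S, "diameter"))
    for (k in seq_len(max(dmax - 1, 1))) {
      expect_equal(unname(cd_matrix(g, k)),
                   unname(oracle_cd_matrix(g, k)),
                   tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("CD scores are in [0,1], symmetric, and equal across K4", {
  k4 <- similarity_scores(make_toy("complete", 4), "CD")
  expect_equal(nrow(k4), 6)
  expect_true(all(abs(k4$score - k4$score[1]) < 1e-12))
  for (g in small_fixtures()) {
    S <- cd_matrix(g)
    expect_symmetric(S)
    expect_true(all(S >= 0 & S <= 1))
  }
})

test_that("threshold changes the score: P3 at k=1 vs k=2", {
  p3 <- make_toy("path", 3)
  s1 <- cd_matrix(p3, 1)["1", "3"]
  s2 <- cd_matrix(p3, 2)["1", "3"]
  # rows of A+I: (1,1,0) vs (0,1,1) -> 1/2; with the 1/2 entries -> 2/2.25
  expect_equal(s1, 0.5, tolerance = 1e-12)
  expect_equal(s2, 2 / 2.25, tolerance = 1e-12)
})

test_that("k above the diameter is clamped with a notice", {
  p3 <- make_toy("path", 3)
  expect_message(S <- cd_matrix(p3, 10), "clamped")
  expect_equal(unname(S), unname(cd_matrix(p3, 2)), ignore_attr = TRUE)
})

test_that("structurally equivalent nodes get identical CD scores", {
  bases <- list(make_toy("complete", 4),
                make_er(10, 0.3, seed = 31, connected = TRUE),
                make_ba(12, 2, seed = 7))
  for (b in bases) {
    nm <- igraph::V(b)$name
    g <- make_struct_equiv(b, nm[2])
    S <- cd_matrix(g)
    twin <- paste0(nm[2], "_twin")
    others <- setdiff(rownames(S), c(nm[2], twin))
    expect_lt(max(abs(S[nm[2], others] - S[twin, others])), 1e-12)
  }
})

test_that("LD sums the base score over distinct common-neighbor pairs", {
  # star: leaf pairs share only the center -> all zero
  star <- make_toy("star", 5)
  L <- ld_matrix(star, cd_matrix(star))
  leaves <- as.character(2:6)
  expect_true(all(L[leaves, leaves] == 0))
  # K4 pair (1,2): common neighbors {3,4} -> single term s_34
  k4 <- make_toy("complete", 4)
  CD4 <- cd_matrix(k4)
  L4 <- ld_matrix(k4, CD4)
  expect_equal(L4["1", "2"], CD4["3", "4"], tolerance = 1e-12)
  # include_self adds one diagonal term (=1 for CD) per common neighbor
  Ls <- ld_matrix(k4, CD4, include_self = TRUE)
  expect_equal(Ls["1", "2"], L4["1", "2"] + 2, tolerance = 1e-12)
  p3 <- make_toy("path", 3)
  expect_true(all(ld_matrix(p3, cd_matrix(p3)) == 0))  # single CN -> 0
})

test_that("LD and the composed CD-LD/CD*LD tables match naive oracles", {
  for (g in small_fixtures()) {
    CD <- cd_matrix(g)
    oCD <- oracle_cd_matrix(g)
    for (self in c(FALSE, TRUE)) {
      expect_equal(unname(ld_matrix(g, CD, include_self = self)),
                   unname(oracle_ld_matrix(g, oCD, include_self = self)),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
    SL <- similarity_matrix(g, "CD-LD")
    expect_equal(unname(SL), unname(oracle_ld_matrix(g, oCD)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    SP <- similarity_matrix(g, "CD*LD")
    prod <- oCD * oracle_ld_matrix(g, oCD)
    diag(prod) <- 0
    expect_equal(unname(SP), unname(prod), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(SL >= 0) && all(SP >= 0))
  }
})

test_that("CDI multiplies CD by the training-graph degree product", {
  g <- make_er(10, 0.35, seed = 41, connected = TRUE)
  CDI <- similarity_matrix(g, "CDI")
  CD <- cd_matrix(g)
  deg <- igraph::degree(g)
  expect_equal(unname(CDI), unname(CD * outer(deg, deg)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # CDI ranks pairs exactly like the CD x PA product
  PA <- similarity_matrix(g, "PA")
  ut <- upper.tri(CDI)
  expect_identical(order(CDI[ut]), order((CD * PA)[ut]))
  # degree-1 endpoints leave CD unchanged
  p2 <- make_toy("path", 2)
  expect_equal(unname(similarity_matrix(p2, "CDI")),
               unname(cd_matrix(p2)), ignore_attr = TRUE)
})

test_that("suffixed index names select the threshold", {
  g <- make_er(15, 0.2, seed = 51, connected = TRUE)
  expect_equal(similarity_matrix(g, "CD-2"),
               similarity_matrix(g, "CD", k = 2))
  s <- similarity_scores(g, "CD-LD-2")
  expect_equal(s$index[1], "CD-LD-2")
  expect_error(similarity_matrix(g, "NOPE"), "unknown")
})

test_that("score tables are symmetric in the pair and sorted descending", {
  g <- make_er(12, 0.3, seed = 61, connected = TRUE)
  for (ix in c("CD", "CD-LD", "CDI", "CN")) {
    tb <- similarity_scores(g, ix)
    expect_equal(nrow(tb), choose(12, 2))
    expect_true(all(diff(tb$score) <= 1e-12))
    expect_false(any(tb$node_u == tb$node_v))
    S <- similarity_matrix(g, ix)
    expect_equal(tb$score,
                 S[cbind(tb$node_u, tb$node_v)], tolerance = 1e-12)
    expect_equal(S[cbind(tb$node_u, tb$node_v)],
                 S[cbind(tb$node_v, tb$node_u)], tolerance = 1e-12)
  }
})
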