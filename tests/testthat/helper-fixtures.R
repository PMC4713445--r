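# Shared fixture graphs. Small (n <= 12) ones feed the brute-force oracle
# suites; the list includes a disconnected instance and a structurally
# equivalent twin pair on purpose.

small_fixtures <- function() {
  tw <- make_struct_equiv(make_er(9, 0.35, seed = 107, connected = TRUE), "3")
  list(
    path4 = make_toy("path", 4),
    path6 = make_toy("path", 6),
    cycle5 = make_toy("cycle", 5),
    star5 = make_toy("star", 5),
    complete4 = make_toy("complete", 4),
    complete5 = make_toy("complete", 5),
    er12 = make_er(12, 0.3, seed = 101, connected = TRUE),
    er12_sparse = make_er(12, 0.18, seed = 103),  # typically disconnected
    twin9 = tw
  )
}

expect_symmetric <- function(S, tol = 1e-12) {
  expect_lt(max(abs(S - t(S))), tol)
}
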