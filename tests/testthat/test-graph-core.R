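test_that("sgraph validates its invariants", {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  X <- matrix(0, 2, 1); Y <- cbind(c(1, 0), c(0, 1))
  expect_s3_class(sgraph(A, X, Y), "sgraph")
  # asymmetric adjacency
  B <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2))
  expect_error(sgraph(B, X, Y), class = "semigraph_validation_error")
  # stored self-loop
  D <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 1), x = 1, dims = c(2, 2))
  expect_error(sgraph(D, X, Y), class = "semigraph_validation_error")
  # overlapping masks
  expect_error(sgraph(A, X, Y, masks = list(train = 1L, val = 1L, test = 2L)),
               class = "semigraph_validation_error")
  # non-binary labels
  expect_error(sgraph(A, X, cbind(c(2, 0), c(0, 1))),
               class = "semigraph_validation_error")
})

test_that("symmetric normalization matches hand-evaluated cases", {
  # single isolated node: (D+I)^{-1/2}(A+I)(D+I)^{-1/2} = [[1]]
  g1 <- single_node_graph()
  expect_equal(as.matrix(normalize_adjacency(g1, "M2")$A_hat), matrix(1, 1, 1))
  # two nodes, one edge: (D+I) = 2I so every entry is 1/2
  g2 <- two_node_graph()
  expect_equal(as.matrix(normalize_adjacency(g2, "M2")$A_hat),
               matrix(0.5, 2, 2))
  # 3-node path, degrees (1,2,1): off-diagonal 1/sqrt(2*3), middle 1/3
  g3 <- path3_graph()
  Ah <- as.matrix(normalize_adjacency(g3, "M2")$A_hat)
  expect_equal(Ah[1, 2], 1 / sqrt(6))
  expect_equal(Ah[2, 2], 1 / 3)
  expect_equal(Ah[1, 1], 1 / 2)
  expect_true(isSymmetric(Ah))
})

test_that("all four normalization strategies satisfy their contracts", {
  g <- er_graph(30, 0.15, seed = 42)
  d <- Matrix::rowSums(g$adjacency)
  m1 <- normalize_adjacency(g, "M1")
  expect_equal(as.matrix(m1$A_hat), as.matrix(g$adjacency + Matrix::Diagonal(30)))
  m2 <- normalize_adjacency(g, "M2")
  expect_true(isSymmetric(as.matrix(m2$A_hat)))
  m3 <- normalize_adjacency(g, "M3")
  expect_equal(Matrix::rowSums(m3$A_hat), rep(1, 30), tolerance = 1e-8,
               ignore_attr = TRUE)
  m4 <- normalize_adjacency(g, "M4")
  # default gate w = (1, 0): column j of M4 is M2 scaled by (d_j+1)/(d_j+2)
  gate <- (d + 1) / (d + 2)
  expect_equal(as.matrix(m4$A_hat),
               as.matrix(m2$A_hat %*% Matrix::Diagonal(30, gate)),
               ignore_attr = TRUE)
  for (m in list(m1, m2, m3, m4)) expect_true(all(as.matrix(m$A_hat) >= 0))
})

test_that("isolated nodes are handled by the self-loop, not rejected", {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  g <- sgraph(A, matrix(0, 3, 1), matrix(c(1, 0, 1), 3, 1))
  Ah <- as.matrix(normalize_adjacency(g, "M2")$A_hat)
  expect_equal(Ah[3, 3], 1)
  expect_equal(Ah[3, 1:2], c(0, 0))
})

test_that("spectral radius of the symmetric normalization is at most one", {
  expect_equal(spectral_radius(normalize_adjacency(single_node_graph(), "M2")), 1)
  # two-node single edge: eigenvalues of 0.5 * ones are {0, 1}
  expect_equal(spectral_radius(normalize_adjacency(two_node_graph(), "M2")), 1)
  for (s in 1:20) {
    g <- er_graph(50, 0.1, seed = s)
    expect_lte(spectral_radius(normalize_adjacency(g, "M2")), 1 + 1e-8)
  }
})

test_that("mixed-order operator averages adjacency powers", {
  g <- two_node_graph()
  op <- normalize_adjacency(g, "M2")
  expect_error(mixed_order_operator(op, -1), class = "semigraph_argument_error")
  # K = 0: identity
  op0 <- mixed_order_operator(op, 0)
  expect_equal(as.matrix(op0$A_bar), diag(2))
  # K = 1: (I + A_hat) / 2
  op1 <- mixed_order_operator(op, 1)
  expect_equal(as.matrix(op1$A_bar), matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  # random graph matches dense matrix-power oracle
  g20 <- er_graph(20, 0.2, seed = 7)
  oph <- normalize_adjacency(g20, "M2")
  op4 <- mixed_order_operator(oph, 4)
  Ah <- as.matrix(oph$A_hat)
  oracle <- Reduce(`+`, lapply(0:4, function(k) {
    M <- diag(20); for (i in seq_len(k)) M <- M %*% Ah; M
  })) / 5
  expect_equal(as.matrix(op4$A_bar), oracle, tolerance = 1e-8)
  X <- matrix(rnorm(20 * 3), 20)
  expect_equal(propagate(op4, X), oracle %*% X, tolerance = 1e-8)
})

test_that("sqrt(d+1) is a fixed vector of the M2 mixed-order operator", {
  g <- er_graph(40, 0.12, seed = 3)
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 5)
  v <- sqrt(Matrix::rowSums(g$adjacency) + 1)
  expect_equal(propagate(op, matrix(v)), matrix(v), tolerance = 1e-10)
})

test_that("propagate validates shapes and respects the lazy path", {
  g <- er_graph(15, 0.2, seed = 5)
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 2)
  expect_error(propagate(op, matrix(0, 10, 2)), class = "semigraph_validation_error")
  # lazy operator (no materialized A_bar) gives the same result
  lazy <- op; lazy$A_bar <- NULL
  X <- matrix(rnorm(30), 15)
  expect_equal(propagate(lazy, X), propagate(op, X))
})
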