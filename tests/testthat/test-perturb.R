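test_that("dropnode masks whole rows with unbiased rescaling", {
  X <- matrix(c(2, 4), 2, 1)
  expect_equal(dropnode(X, 0), X)
  expect_error(dropnode(X, 1), class = "semigraph_argument_error")
  expect_error(dropnode(X, -0.1), class = "semigraph_argument_error")
  # find a seed whose mask keeps row 1 and drops row 2, then check the
  # surviving row is scaled by 1/(1-delta) = 2
  seed <- Find(function(s) {
    out <- dropnode(X, 0.5, s); out[1] != 0 && out[2] == 0
  }, 1:50)
  expect_equal(dropnode(X, 0.5, seed), matrix(c(4, 0), 2, 1))
  # determinism
  Xr <- matrix(rnorm(50), 10)
  expect_identical(dropnode(Xr, 0.3, 99), dropnode(Xr, 0.3, 99))
  # rows are zeroed jointly
  out <- dropnode(Xr, 0.5, 7)
  zeroed <- rowSums(out != 0) == 0
  expect_true(all(out[!zeroed, ] == Xr[!zeroed, ] * 2))
})

test_that("dropout masks single elements with unbiased rescaling", {
  X <- matrix(c(1, 1), 1, 2)
  expect_equal(dropout_elements(X, 0), X)
  seed <- Find(function(s) {
    out <- dropout_elements(X, 0.5, s); out[1] == 0 && out[2] != 0
  }, 1:50)
  expect_equal(dropout_elements(X, 0.5, seed), matrix(c(0, 2), 1, 2))
})

test_that("perturbations are unbiased in expectation (Monte Carlo)", {
  X <- matrix(rnorm(20 * 3), 20)
  for (fn in list(dropnode, dropout_elements)) {
    acc <- 0
    B <- 3000L
    for (b in seq_len(B)) acc <- acc + fn(X, 0.2, b)
    se <- sqrt(X^2 * (0.2 / 0.8) / B)  # elementwise sd of the MC mean
    expect_true(all(abs(acc / B - X) <= 4 * se + 1e-8))
  }
})

test_that("random_propagate builds independent reproducible augmentations", {
  g <- small_bench(2)
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 3)
  # delta = 0: all augmentations equal the deterministic propagation
  b0 <- random_propagate(g, op, S = 3, delta = 0, seed = 1)
  expect_equal(b0$X_bar_list[[1]], propagate(op, g$features))
  expect_equal(b0$X_bar_list[[2]], b0$X_bar_list[[3]])
  # determinism: same seed, bit-identical batch
  b1 <- random_propagate(g, op, S = 2, delta = 0.2, seed = 5)
  b2 <- random_propagate(g, op, S = 2, delta = 0.2, seed = 5)
  expect_identical(b1$X_bar_list, b2$X_bar_list)
  # augmentations differ from each other
  expect_false(identical(b1$X_bar_list[[1]], b1$X_bar_list[[2]]))
  # graph topology untouched by feature perturbation
  before <- g$adjacency
  invisible(random_propagate(g, op, S = 2, delta = 0.5, seed = 9))
  expect_identical(g$adjacency, before)
  expect_error(random_propagate(g, op, S = 0, delta = 0.2, seed = 1),
               class = "semigraph_argument_error")
})

test_that("two-node worked example: propagation of a masked batch", {
  g <- two_node_graph()
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 1)
  # mask drops node 2 at delta = 0.5: X_tilde = [[2],[0]]
  Xt <- matrix(c(2, 0), 2, 1)
  expect_equal(propagate(op, Xt), matrix(c(1.5, 0.5), 2, 1))
})

test_that("analytic DropNode variance matches the hand case and Monte Carlo", {
  g <- two_node_graph()
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 1)
  # A_bar = [[.75,.25],[.25,.75]], X = [[1],[1]], W = 1, delta = .5:
  # Var_0 = 1 * (0.75^2 + 0.25^2) = 0.625
  v <- analytic_variance_dropnode(op, g$features, 1, 0.5)
  expect_equal(v, c(0.625, 0.625))
  expect_equal(analytic_variance_dropnode(op, g$features, 1, 0), c(0, 0))
  expect_error(analytic_variance_dropnode(op, g$features, 1, 1),
               class = "semigraph_argument_error")
  # Monte Carlo on a random small graph
  gg <- small_bench(3, n = 12, C = 3)
  opp <- mixed_order_operator(normalize_adjacency(gg, "M2"), 2)
  W <- rnorm(ncol(gg$features))
  va <- analytic_variance_dropnode(opp, gg$features, W, 0.2)
  Ab <- as.matrix(opp$A_bar)
  xw <- as.numeric(gg$features %*% W)
  set.seed(11)
  M <- matrix(rbinom(12 * 20000, 1, 0.8), 12) / 0.8
  draws <- Ab %*% (M * xw)
  emp <- apply(draws, 1, var)
  expect_true(all(abs(emp - va) / va < 0.05))
})

test_that("element-mask dropout variance differs from DropNode and matches MC", {
  # single node, X = [1,1], W = (1,1): dropnode variance uses (x'W)^2 = 4,
  # dropout uses sum_f (x_f W_f)^2 = 2
  g1 <- single_node_graph(d = 2)
  g1$features[] <- 1
  op1 <- mixed_order_operator(normalize_adjacency(g1, "M2"), 0)
  expect_equal(analytic_variance_dropout(op1, g1$features, c(1, 1), 0.5), 2)
  expect_equal(analytic_variance_dropnode(op1, g1$features, c(1, 1), 0.5), 4)
  # Monte Carlo
  gg <- small_bench(4, n = 12, C = 3)
  opp <- mixed_order_operator(normalize_adjacency(gg, "M2"), 2)
  W <- rnorm(ncol(gg$features))
  vd <- analytic_variance_dropout(opp, gg$features, W, 0.2)
  Ab <- as.matrix(opp$A_bar)
  XW <- sweep(gg$features, 2, W, `*`)
  set.seed(12)
  emp <- apply(replicate(20000, {
    M <- matrix(rbinom(length(XW), 1, 0.8), nrow(XW)) / 0.8
    as.numeric(Ab %*% rowSums(XW * M))
  }), 1, var)
  expect_true(all(abs(emp - vd) / vd < 0.05))
})

test_that("DropNode regularizer weights variance by prediction uncertainty", {
  g <- two_node_graph()
  op <- mixed_order_operator(normalize_adjacency(g, "M2"), 1)
  X <- g$features; W <- 1
  # confident predictions contribute nothing
  expect_equal(regularizer_dropnode(op, X, W, c(0, 1), 0.5), 0)
  # z = 0.5 attains the per-node peak weight 0.0625
  expect_equal(regularizer_dropnode(op, X, W, c(0.5, 0.5), 0.5),
               0.0625 * (0.625 + 0.625))
  zs <- seq(0.05, 0.95, by = 0.05)
  w <- zs^2 * (1 - zs)^2
  expect_equal(zs[which.max(w)], 0.5)
  expect_equal(max(w), 0.0625)
})
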