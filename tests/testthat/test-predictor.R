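test_that("degenerate forward passes match closed forms", {
  g <- single_node_graph(d = 2, C = 2)
  p <- predictor_init(2, 2, hidden = 4, activation = "softmax", dropout = 0, seed = 1)
  # zero weights everywhere: logits 0, softmax = (1/2, 1/2)
  for (f in semigraph:::param_fields(p)) p[[f]][] <- 0
  Z <- att_mlp_forward(matrix(0, 1, 2), g, p)
  expect_equal(as.numeric(Z), c(0.5, 0.5))
  # single node: attention softmax over the self-loop alone is weight 1,
  # so the attention branch reduces to W3 on the node's own features
  p2 <- predictor_init(2, 2, hidden = 4, activation = "softmax", dropout = 0, seed = 2)
  X <- matrix(c(0.3, -0.7), 1, 2)
  fw <- att_mlp_forward(X, g, p2, return_cache = TRUE)
  expect_equal(as.numeric(fw$cache$alpha), 1)
  expect_equal(fw$cache$m, X, ignore_attr = TRUE)
})

test_that("forward pass matches an independent hand evaluation", {
  g <- two_node_graph(d = 2)
  g$features <- matrix(c(1, 2, -1, 0.5), 2, 2)
  p <- predictor_init(2, 2, hidden = 2, activation = "softmax", dropout = 0, seed = 3)
  p$W1 <- matrix(c(1, 0, 0, 1), 2); p$b1 <- c(0.1, -0.2)
  p$W2 <- matrix(c(0.5, -0.5, 0.2, 0.3), 2); p$b2 <- c(0, 0.1)
  p$W3 <- matrix(c(-0.3, 0.4, 0.6, -0.1), 2); p$b3 <- c(0.05, 0)
  p$u <- c(0.2, -0.1); p$v <- c(0.3, 0.25)
  X <- g$features
  # oracle: explicit re-derivation with plain loops
  H1 <- pmax(X %*% p$W1 + rep(1, 2) %o% p$b1, 0)
  lmlp <- H1 %*% p$W2 + rep(1, 2) %o% p$b2
  lrel <- function(x) ifelse(x > 0, x, 0.2 * x)
  Z <- matrix(0, 2, 2)
  m <- matrix(0, 2, 2)
  for (i in 1:2) {
    nb <- 1:2  # both nodes neighbour each other, self included
    s <- sapply(nb, function(j) lrel(sum(p$u * X[i, ]) + sum(p$v * X[j, ])))
    a <- exp(s - max(s)); a <- a / sum(a)
    m[i, ] <- colSums(a * X[nb, ])
  }
  latt <- m %*% p$W3 + rep(1, 2) %o% p$b3
  L <- lmlp + latt
  oracle <- t(apply(L, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(att_mlp_forward(X, g, p), oracle, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(4)
  g <- path3_graph()
  X <- matrix(rnorm(6), 3, 2)
  Y <- g$labels
  ed <- semigraph:::attention_edges(g)
  for (combine in c("sum", "concat")) {
    p <- predictor_init(2, 2, hidden = 3, combine = combine,
                        activation = "softmax", dropout = 0, seed = 5)
    fw <- att_mlp_forward(X, g, p, edges = ed, return_cache = TRUE)
    G <- fw$Z - Y  # d/dlogits of -sum(Y log Z) through softmax
    gr <- semigraph:::att_mlp_backward(G, p, fw$cache)
    loss <- function(pp) -sum(Y * log(att_mlp_forward(X, g, pp, edges = ed)))
    for (f in semigraph:::param_fields(p)) {
      ng <- p[[f]]
      for (k in seq_along(ng)) {
        pp <- p; pp[[f]][k] <- pp[[f]][k] + 1e-6; l1 <- loss(pp)
        pp[[f]][k] <- pp[[f]][k] - 2e-6; l2 <- loss(pp)
        ng[k] <- (l1 - l2) / 2e-6
      }
      expect_equal(gr[[f]], ng, tolerance = 1e-5, ignore_attr = TRUE,
                   label = paste(combine, f))
    }
  }
})

test_that("forward pass is permutation-equivariant", {
  set.seed(6)
  g <- small_bench(5, n = 20, C = 3)
  p <- predictor_init(8, 3, hidden = 6, activation = "softmax", dropout = 0, seed = 7)
  Xb <- propagate(mixed_order_operator(normalize_adjacency(g, "M2"), 2), g$features)
  Z <- att_mlp_forward(Xb, g, p)
  perm <- sample(20)
  gp <- sgraph(g$adjacency[perm, perm], g$features[perm, ], g$labels[perm, ])
  Zp <- att_mlp_forward(Xb[perm, ], gp, p)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-12)
})

test_that("label-count mismatch is a validation error", {
  g <- two_node_graph()
  p <- predictor_init(1, 3, hidden = 2, seed = 1)  # C = 3 vs graph C = 2
  expect_error(att_mlp_forward(g$features, g, p),
               class = "semigraph_validation_error")
})

test_that("sharpening transforms distributions as specified", {
  Z <- rbind(c(0.8, 0.2), c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(sharpen(Z, 1), Z)
  expect_equal(sharpen(Z, 0.5)[2, ], c(0.5, 0.5))
  # (0.8, 0.2) at T = 0.5: (0.64, 0.04) / 0.68
  expect_equal(sharpen(Z, 0.5)[1, ], c(0.64, 0.04) / 0.68, tolerance = 1e-5)
  expect_equal(sharpen(Z, 0.5)[1, ], c(0.94118, 0.05882), tolerance = 1e-4)
  # rows stay distributions
  out <- sharpen(matrix(runif(30), 10, 3) + 0.01, 0.3)
  expect_equal(rowSums(out), rep(1, 10))
  # T -> 0 approaches one-hot argmax on non-tied rows
  low <- sharpen(rbind(c(0.6, 0.3, 0.1)), 0.01)
  expect_gt(max(low), 0.999)
  expect_equal(which.max(low), 1L)
  expect_error(sharpen(Z, 0), class = "semigraph_argument_error")
  expect_error(sharpen(rbind(c(-0.1, 1.1)), 0.5), class = "semigraph_validation_error")
  expect_error(sharpen(rbind(c(0, 0)), 0.5), class = "semigraph_validation_error")
})

test_that("Bernoulli sharpening acts per label", {
  P <- rbind(c(0.8, 0.5, 0.2))
  out <- sharpen_bernoulli(P, 0.5)
  expect_equal(out[1, 2], 0.5)
  expect_equal(out[1, 1], 0.64 / 0.68, tolerance = 1e-12)
  expect_equal(out[1, 3], 1 - out[1, 1], tolerance = 1e-12)
  expect_equal(sharpen_bernoulli(P, 1), P)
})

test_that("parameters round-trip through the text archive", {
  p <- predictor_init(3, 2, hidden = 4, seed = 8)
  path <- tempfile(fileext = ".txt")
  params_save(p, path)
  q <- params_load(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
})
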