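# Small deterministic fixtures shared across the suite.

# two nodes joined by one edge
two_node_graph <- function(d = 1L) {
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  sgraph(A, matrix(1, 2, d), cbind(c(1, 0), c(0, 1)),
         masks = list(train = 1L, val = integer(), test = 2L))
}

# path on three nodes 1-2-3
path3_graph <- function() {
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1, dims = c(3, 3))
  sgraph(A, matrix(rnorm(6), 3), cbind(c(1, 0, 1), c(0, 1, 0)),
         masks = list(train = 1:2, val = 3L, test = integer()))
}

single_node_graph <- function(d = 2L, C = 2L) {
  A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(1, 1))
  Y <- matrix(0, 1, C); Y[1, 1] <- 1
  sgraph(A, matrix(0, 1, d), Y, masks = list(train = 1L, val = integer(), test = integer()))
}

# Erdos-Renyi sgraph with dummy features/labels
er_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1L, p)
  A <- A + t(A)
  sgraph(methods::as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix"),
         matrix(rnorm(n * 2), n), cbind(rep(1, n), rep(0, n)),
         masks = list(train = 1L, val = integer(), test = integer()))
}

# small generated benchmark for fast training tests
small_bench <- function(seed = 1L, n = 150L, C = 4L) {
  generate_multilabel_graph(synth_config(
    n_nodes = n, n_labels = C, taxonomy_depth = min(2L, C - 1L), feature_dim = 8L,
    labels_per_node = 1.5, avg_degree = 8, labeled_fraction = 0.15,
    single_label = TRUE, seed = seed))
}

fast_cfg <- function(...) {
  run_config(activation = "softmax", hidden = 16L, S = 2L, epochs = 15L,
             patience = 15L, lr = 1e-2, ...)
}

test_accuracy <- function(fit, graph) {
  te <- graph$masks$test
  Z <- predict(fit, newgraph = graph)
  mean(max.col(Z[te, , drop = FALSE], ties.method = "first") ==
       max.col(graph$labels[te, , drop = FALSE]))
}
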