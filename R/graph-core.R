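#' Construct a graph dataset for semi-supervised node classification
#'
#' Bundles a sparse undirected adjacency matrix, dense node features,
#' (multi-label) node annotations and disjoint train/validation/test masks
#' into a validated `sgraph` object, the input type consumed by every other
#' function in the package.
#'
#' @param adjacency n x n symmetric binary adjacency (base or `Matrix` sparse
#'   matrix). Self-loops must not be stored; normalization adds them.
#' @param features n x d numeric feature matrix.
#' @param labels n x C binary label indicator matrix; rows may contain several
#'   ones (multi-label) or exactly one (single-label mode).
#' @param masks named list with integer node index vectors `train`, `val`,
#'   `test` (1-based, pairwise disjoint). Any may be empty.
#' @param label_names optional character vector of length C.
#' @return An object of class `sgraph`: a list with elements `n_nodes`,
#'   `adjacency` (`dgCMatrix`), `features`, `labels`, `masks`, `label_names`.
#' @examples
#' A <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(2, 2), symmetric = TRUE)
#' g <- sgraph(A, matrix(rnorm(4), 2), matrix(c(1, 0, 0, 1), 2),
#'             masks = list(train = 1L, val = integer(), test = 2L))
#' @export
sgraph <- function(adjacency, features, labels,
                   masks = list(train = integer(), val = integer(), test = integer()),
                   label_names = NULL) {
  A <- methods::as(methods::as(methods::as(adjacency, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (ncol(A) != n) stop_validation("adjacency must be square")
  if (!Matrix::isSymmetric(A, tol = 0)) stop_validation("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop_validation("adjacency must have a zero diagonal (no stored self-loops)")
  A <- Matrix::drop0(A)
  if (length(A@x) && any(A@x != 1)) stop_validation("adjacency must be binary")
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != n) stop_validation("features must have one row per node")
  if (nrow(labels) != n) stop_validation("labels must have one row per node")
  if (any(!labels %in% c(0, 1))) stop_validation("labels must be a 0/1 indicator matrix")
  masks <- lapply(masks, function(m) sort(as.integer(m)))
  for (nm in c("train", "val", "test")) masks[[nm]] <- masks[[nm]] %||% integer()
  all_idx <- unlist(masks, use.names = FALSE)
  if (anyDuplicated(all_idx)) stop_validation("masks must be pairwise disjoint")
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > n))
    stop_validation("mask indices out of range 1..n")
  structure(list(n_nodes = n, adjacency = A, features = features, labels = labels,
                 masks = masks[c("train", "val", "test")],
                 label_names = label_names %||% colnames(labels)),
            class = "sgraph")
}

#' @export
print.sgraph <- function(x, ...) {
  cat(sprintf("sgraph: %d nodes, %d edges, %d features, %d labels\n",
              x$n_nodes, Matrix::nnzero(x$adjacency) / 2, ncol(x$features), ncol(x$labels)))
  cat(sprintf("masks: train %d / val %d / test %d\n",
              length(x$masks$train), length(x$masks$val), length(x$masks$test)))
  invisible(x)
}

node_degrees <- function(graph) as.numeric(Matrix::rowSums(graph$adjacency))

#' Normalize an adjacency matrix for feature propagation
#'
#' Builds the propagation matrix \eqn{\hat A} under one of four strategies:
#' \describe{
#'   \item{M1}{no normalization, \eqn{A + I};}
#'   \item{M2}{symmetric degree normalization with self-loops,
#'     \eqn{\hat A = (D+I)^{-1/2}(A+I)(D+I)^{-1/2}}, whose spectrum lies in
#'     \eqn{[-1, 1]};}
#'   \item{M3}{row normalization of \eqn{A + I} (a stochastic matrix);}
#'   \item{M4}{adaptive: M2 post-multiplied by a per-node diagonal gate
#'     \eqn{g_i = \sigma(w_1 \log(d_i+1) + w_2 \lVert x_i \rVert)}.}
#' }
#' Isolated nodes are well-defined under every strategy because of the added
#' self-loop.
#'
#' @param graph an `sgraph`.
#' @param strategy one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param gate_w length-2 numeric weights of the M4 gate (default `c(1, 0)`,
#'   i.e. a fixed structural gate \eqn{g_i = (d_i+1)/(d_i+2)}).
#' @return A `propagation_operator`: list with `strategy`, `A_hat` (sparse),
#'   `K` (0 until [mixed_order_operator()] fills it) and `A_bar` (`NULL`).
#' @export
normalize_adjacency <- function(graph, strategy = c("M2", "M1", "M3", "M4"),
                                gate_w = c(1, 0)) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(graph, "sgraph"))
  A <- graph$adjacency
  n <- graph$n_nodes
  AI <- A + Matrix::Diagonal(n)
  d <- node_degrees(graph)
  A_hat <- switch(strategy,
    M1 = AI,
    M2 = {
      s <- 1 / sqrt(d + 1)
      Matrix::Diagonal(n, s) %*% AI %*% Matrix::Diagonal(n, s)
    },
    M3 = Matrix::Diagonal(n, 1 / (d + 1)) %*% AI,
    M4 = {
      s <- 1 / sqrt(d + 1)
      base <- Matrix::Diagonal(n, s) %*% AI %*% Matrix::Diagonal(n, s)
      g <- sigmoid(gate_w[1] * log(d + 1) + gate_w[2] * sqrt(rowSums(graph$features^2)))
      base %*% Matrix::Diagonal(n, g)
    })
  structure(list(strategy = strategy, A_hat = methods::as(A_hat, "CsparseMatrix"),
                 K = 0L, A_bar = NULL, n = n),
            class = "propagation_operator")
}

#' @export
print.propagation_operator <- function(x, ...) {
  cat(sprintf("propagation_operator: strategy %s, n = %d, K = %d (A_bar %s)\n",
              x$strategy, x$n, x$K,
              if (is.null(x$A_bar)) "lazy" else "materialized"))
  invisible(x)
}

#' Spectral radius of a propagation matrix
#'
#' Largest absolute eigenvalue of \eqn{\hat A}. For the symmetric M2
#' normalization this is at most 1 for every simple undirected graph, the
#' stability property that keeps repeated propagation from blowing up.
#'
#' @param op a `propagation_operator`.
#' @return Non-negative scalar.
#' @export
spectral_radius <- function(op) {
  stopifnot(inherits(op, "propagation_operator"))
  M <- as_dense(op$A_hat)
  if (isSymmetric(M, tol = 1e-12)) {
    max(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    max(Mod(eigen(M, only.values = TRUE)$values))
  }
}

# threshold above which A_bar is never materialized densely
.DENSE_LIMIT <- 2000L

#' Mixed-order propagation operator
#'
#' Fills the mixed-order average \eqn{\bar A = \frac{1}{K+1}\sum_{k=0}^{K}
#' \hat A^k}, which aggregates features from hop 0 (the node itself) out to
#' hop K, damping over-smoothing relative to a single high power. For graphs
#' with more than 2000 nodes the matrix is kept lazy and applied by K sparse
#' mat-vec sweeps in [propagate()].
#'
#' @param op a `propagation_operator` from [normalize_adjacency()].
#' @param K non-negative integer propagation order.
#' @return The operator with `K` set and `A_bar` materialized when small.
#' @export
mixed_order_operator <- function(op, K) {
  stopifnot(inherits(op, "propagation_operator"))
  if (length(K) != 1L || is.na(K) || K < 0 || K != round(K))
    stop_argument("K must be a single non-negative integer")
  op$K <- as.integer(K)
  if (op$n <= .DENSE_LIMIT) {
    acc <- Matrix::Diagonal(op$n)
    P <- Matrix::Diagonal(op$n)
    if (K > 0) for (k in seq_len(K)) {
      P <- op$A_hat %*% P
      acc <- acc + P
    }
    op$A_bar <- acc / (K + 1)
  } else {
    op$A_bar <- NULL
  }
  op
}

#' Apply the mixed-order operator to a feature matrix
#'
#' Computes \eqn{\bar A X} by iterated sparse products
#' \eqn{\frac{1}{K+1}\sum_k \hat A^k X}; never forms dense matrix powers.
#'
#' @param op a `propagation_operator` with `K` set (see
#'   [mixed_order_operator()]).
#' @param X numeric matrix with `op$n` rows.
#' @return Dense numeric matrix of the same shape as `X`.
#' @export
propagate <- function(op, X) {
  stopifnot(inherits(op, "propagation_operator"))
  X <- as.matrix(X)
  if (nrow(X) != op$n) stop_validation("X has ", nrow(X), " rows; operator expects ", op$n)
  acc <- X
  P <- X
  if (op$K > 0) for (k in seq_len(op$K)) {
    P <- as.matrix(op$A_hat %*% P)
    acc <- acc + P
  }
  acc / (op$K + 1)
}
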