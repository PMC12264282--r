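# DropNode / dropout feature perturbation, random propagation, and the
# closed-form variance oracles used to analyze the induced regularization.

#' DropNode perturbation
#'
#' Zeroes entire node feature rows independently with probability `delta` and
#' rescales survivors by \eqn{1/(1-\delta)}, so the perturbed matrix is an
#' unbiased estimate of `X`. The graph topology is untouched (this perturbs
#' features, not edges). At inference time pass `delta = 0`.
#'
#' @param X numeric matrix (nodes x features).
#' @param delta drop probability in `[0, 1)`.
#' @param seed integer seed making the mask reproducible, or `NULL` to use the
#'   current RNG stream.
#' @return Perturbed matrix of the same shape.
#' @export
dropnode <- function(X, delta, seed = NULL) {
  X <- as.matrix(X)
  check_delta(delta)
  if (delta == 0) return(X)
  keep <- with_seed(seed, stats::rbinom(nrow(X), 1L, 1 - delta))
  X * (keep / (1 - delta))
}

#' Element-wise dropout perturbation
#'
#' Classical dropout on the feature matrix: each entry is zeroed independently
#' with probability `delta` and survivors rescaled by \eqn{1/(1-\delta)}
#' (`X_ij <- eps_ij X_ij / (1-delta)`, `eps_ij ~ Bernoulli(1-delta)`).
#'
#' @inheritParams dropnode
#' @return Perturbed matrix of the same shape.
#' @export
dropout_elements <- function(X, delta, seed = NULL) {
  X <- as.matrix(X)
  check_delta(delta)
  if (delta == 0) return(X)
  keep <- with_seed(seed, matrix(stats::rbinom(length(X), 1L, 1 - delta), nrow(X)))
  X * (keep / (1 - delta))
}

check_delta <- function(delta) {
  if (length(delta) != 1L || is.na(delta) || delta < 0 || delta >= 1)
    stop_argument("delta must lie in [0, 1)")
  invisible(delta)
}

#' Random propagation: S perturb-then-propagate augmentations
#'
#' Draws `S` independent perturbations of the node features (DropNode by
#' default), propagates each through the mixed-order operator
#' (\eqn{\bar X^{(s)} = \bar A \tilde X^{(s)}}), and returns the batch.
#' Augmentation `s` uses seed `seed + s`, so the batch is reproducible and the
#' augmentations are mutually independent streams.
#'
#' @param graph an `sgraph`.
#' @param op a `propagation_operator` with `K` set.
#' @param S number of augmentations (>= 1).
#' @param delta drop probability; `0` disables perturbation.
#' @param mode `"dropnode"`, `"dropout"`, or `"none"`.
#' @param seed integer root seed.
#' @return An `augmented_batch`: list with `S`, `X_tilde_list`, `X_bar_list`,
#'   `delta`, `mode`, `seed`.
#' @export
random_propagate <- function(graph, op, S = 4L, delta = 0.2,
                             mode = c("dropnode", "dropout", "none"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "sgraph"))
  if (S < 1) stop_argument("S must be >= 1")
  X <- graph$features
  if (nrow(X) != op$n) stop_validation("feature matrix and operator disagree on n")
  perturb <- switch(mode,
    dropnode = function(s) dropnode(X, delta, seed + s),
    dropout  = function(s) dropout_elements(X, delta, seed + s),
    none     = function(s) X)
  X_tilde <- lapply(seq_len(S), perturb)
  X_bar <- lapply(X_tilde, function(Xt) propagate(op, Xt))
  structure(list(S = as.integer(S), X_tilde_list = X_tilde, X_bar_list = X_bar,
                 delta = delta, mode = mode, seed = seed),
            class = "augmented_batch")
}

#' @export
print.augmented_batch <- function(x, ...) {
  cat(sprintf("augmented_batch: S = %d, mode = %s, delta = %.3f, seed = %d\n",
              x$S, x$mode, x$delta, x$seed))
  invisible(x)
}

a_bar_dense <- function(op) {
  if (!is.null(op$A_bar)) return(as_dense(op$A_bar))
  as_dense(mixed_order_operator_dense(op))
}

mixed_order_operator_dense <- function(op) {
  acc <- diag(op$n)
  P <- diag(op$n)
  if (op$K > 0) for (k in seq_len(op$K)) {
    P <- as.matrix(op$A_hat %*% P)
    acc <- acc + P
  }
  acc / (op$K + 1)
}

#' Closed-form per-node variance under DropNode
#'
#' For the binary single-layer analysis (a single weight column `W`), the
#' pre-activation of node i after DropNode and mixed-order propagation has
#' variance \eqn{\mathrm{Var}_i = \frac{\delta}{1-\delta} \sum_j (x_j^\top W)^2
#' \bar A_{ij}^2}: whole rows of X are masked, so the squared projection of
#' each neighbour's full feature vector enters.
#'
#' @param op `propagation_operator` with `K` set.
#' @param X feature matrix.
#' @param W numeric weight vector (length `ncol(X)`).
#' @param delta drop probability in `[0, 1)`.
#' @return Numeric vector of per-node variances.
#' @export
analytic_variance_dropnode <- function(op, X, W, delta) {
  check_delta(delta)
  Abar <- a_bar_dense(op)
  xw2 <- as.numeric(as.matrix(X) %*% as.numeric(W))^2
  (delta / (1 - delta)) * as.numeric(Abar^2 %*% xw2)
}

#' Closed-form per-node variance under element-wise dropout
#'
#' Same setting as [analytic_variance_dropnode()] but with independent
#' per-entry masks: \eqn{\mathrm{Var}_i = \frac{\delta}{1-\delta} \sum_j
#' \bar A_{ij}^2 \sum_f (X_{jf} W_f)^2}. Since \eqn{\sum_f (X_{jf}W_f)^2 \le
#' (x_j^\top W)^2} is generally false in either direction, the two oracles
#' genuinely differ; both are verified against simulation in the test suite.
#'
#' @inheritParams analytic_variance_dropnode
#' @return Numeric vector of per-node variances.
#' @export
analytic_variance_dropout <- function(op, X, W, delta) {
  check_delta(delta)
  Abar <- a_bar_dense(op)
  xw2 <- rowSums(sweep(as.matrix(X), 2, as.numeric(W), `*`)^2)
  (delta / (1 - delta)) * as.numeric(Abar^2 %*% xw2)
}

#' DropNode-induced consistency regularizer
#'
#' The quadratic regularizer that consistency training implicitly minimizes
#' under DropNode noise:
#' \eqn{R_{DN} = \frac{\delta}{1-\delta} \sum_i \sum_j (x_j^\top W)^2
#' z_i^2 (1-z_i)^2 \bar A_{ij}^2}.
#' The uncertainty weight \eqn{z_i^2(1-z_i)^2} peaks at \eqn{z_i = 0.5}
#' (value 0.0625) and vanishes at confident predictions.
#'
#' @inheritParams analytic_variance_dropnode
#' @param z per-node predicted probabilities in `[0, 1]`.
#' @return Scalar regularizer value.
#' @export
regularizer_dropnode <- function(op, X, W, z, delta) {
  v <- analytic_variance_dropnode(op, X, W, delta)
  sum(z^2 * (1 - z)^2 * v)
}
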