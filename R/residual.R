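# Residual propagation embeddings: fixed-alpha residual recursion with a
# closed-form fixed point, and depth-adaptive layers with per-layer mixing
# coefficients. Both retain the initial embedding at every depth, the
# mechanism that keeps deep propagation from over-smoothing.

#' One residual propagation step
#'
#' \eqn{H^{(l+1)} = (1-\alpha)\hat A H^{(l)} + \alpha H^{(0)}}: propagate,
#' then mix the initial embedding back in with weight `alpha`.
#'
#' @param H_l current embeddings (n x d matrix).
#' @param H0 initial embeddings (same shape).
#' @param A_hat normalized adjacency (dense or sparse).
#' @param alpha residual mixing weight in `(0, 1)`; `alpha = 1` is allowed as
#'   a degenerate no-propagation mode (with a warning).
#' @return Matrix \eqn{H^{(l+1)}}.
#' @export
mmrp_step <- function(H_l, H0, A_hat, alpha) {
  check_alpha(alpha)
  (1 - alpha) * as.matrix(A_hat %*% H_l) + alpha * as.matrix(H0)
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop_argument("alpha must lie in (0, 1]")
  if (alpha == 1) warning("alpha = 1: residual-only mode, no propagation")
  invisible(alpha)
}

#' Fixed point of the residual propagation recursion
#'
#' Direct linear solve for
#' \eqn{H^{(\infty)} = \alpha (I - (1-\alpha)\hat A)^{-1} H^{(0)}},
#' the unique limit of [mmrp_step()] iteration (the iteration map is a
#' contraction with factor \eqn{(1-\alpha)\rho(\hat A) \le 1-\alpha} under M2
#' normalization).
#'
#' @inheritParams mmrp_step
#' @return Matrix \eqn{H^{(\infty)}}.
#' @export
mmrp_fixed_point <- function(H0, A_hat, alpha) {
  check_alpha(alpha)
  H0 <- as.matrix(H0)
  n <- nrow(H0)
  M <- diag(n) - (1 - alpha) * as_dense(A_hat)
  alpha * solve(M, H0)
}

#' Depth-adaptive residual mixing coefficient
#'
#' Per-layer coefficient \eqn{\alpha_l}. The `"as_printed"` variant is
#' \eqn{\log(l/(l+1)) + \epsilon}, clipped into `[clip_lo, 1 - clip_lo]`
#' because the raw value is negative for small \eqn{\epsilon} and hence not a
#' valid mixing weight. The default `"positive"` variant is the
#' sign-corrected \eqn{\epsilon + \log((l+1)/l)}, strictly decreasing in `l`
#' toward \eqn{\epsilon}: early layers lean on the initial embedding, deep
#' layers mostly propagate.
#'
#' @param l layer index (>= 1).
#' @param epsilon small non-negative tuning constant.
#' @param variant `"positive"` (default) or `"as_printed"`.
#' @param clip_lo clipping floor for the `"as_printed"` variant.
#' @return Scalar coefficient; for `"positive"` additionally capped at 1.
#' @export
dmrm_alpha_schedule <- function(l, epsilon = 0.01,
                                variant = c("positive", "as_printed"),
                                clip_lo = 1e-3) {
  variant <- match.arg(variant)
  if (any(l < 1) || any(l != round(l))) stop_argument("l must be a positive integer")
  if (variant == "as_printed") {
    pmin(pmax(log(l / (l + 1)) + epsilon, clip_lo), 1 - clip_lo)
  } else {
    pmin(epsilon + log((l + 1) / l), 1)
  }
}

# raw (unclipped) printed schedule, used in unit tests of the formula itself
dmrm_alpha_raw <- function(l, epsilon = 0.01) log(l / (l + 1)) + epsilon

#' Depth-adaptive residual forward pass
#'
#' Runs \eqn{H^{(l)} = (1-\alpha_l)\hat A H^{(l-1)} W_1 + \alpha_l H^{(0)}
#' W_l} for `l = 1..L_depth`, with a shared propagation weight `W1` and
#' per-layer residual weights `W_l`. With identity weights and the
#' `"positive"` schedule this reduces to a residual propagation with a
#' decaying mixing coefficient.
#'
#' @param H0 initial embeddings (n x d).
#' @param A_hat normalized adjacency.
#' @param W1 shared d x d weight applied to the propagated branch (default
#'   identity).
#' @param W_list list of `L_depth` d x d weights for the residual branch
#'   (default identities).
#' @param epsilon schedule constant (see [dmrm_alpha_schedule()]).
#' @param L_depth number of layers; `0` returns `H0`.
#' @param variant schedule variant.
#' @return Matrix \eqn{H^{(L)}}.
#' @export
dmrm_forward <- function(H0, A_hat, W1 = NULL, W_list = NULL,
                         epsilon = 0.01, L_depth = 2L,
                         variant = c("positive", "as_printed")) {
  variant <- match.arg(variant)
  H0 <- as.matrix(H0)
  if (L_depth == 0) return(H0)
  d <- ncol(H0)
  W1 <- W1 %||% diag(d)
  W_list <- W_list %||% rep(list(diag(d)), L_depth)
  if (length(W_list) != L_depth) stop_argument("W_list must have L_depth entries")
  H <- H0
  for (l in seq_len(L_depth)) {
    a_l <- dmrm_alpha_schedule(l, epsilon, variant)
    H <- (1 - a_l) * as.matrix(A_hat %*% H) %*% W1 + a_l * H0 %*% W_list[[l]]
  }
  H
}

#' Mean pairwise embedding distance (over-smoothing diagnostic)
#'
#' Mean Euclidean distance between all node pairs; collapses toward zero when
#' propagation over-smooths representations.
#'
#' @param H embedding matrix.
#' @return Scalar mean pairwise distance.
#' @export
embedding_spread <- function(H) {
  mean(stats::dist(as.matrix(H)))
}
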