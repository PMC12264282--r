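# Attention + MLP prediction head. Two branches run on the propagated
# features: a single-head additive attention over graph neighbours (self
# included) and a 2-layer MLP; their class logits are summed (or the branch
# representations concatenated) and passed through softmax (single-label) or
# per-label sigmoid (multi-label). Gradients are hand-derived; the whole head
# is plain dense linear algebra at the scale this package targets.

#' Initialize predictor parameters
#'
#' Xavier-uniform initialization of the attention + MLP head, deterministic
#' given `seed`.
#'
#' @param d input feature dimension.
#' @param C number of labels/classes.
#' @param hidden MLP hidden width (default 128).
#' @param combine `"sum"` (add branch logits) or `"concat"` (concatenate
#'   branch representations before one linear output layer).
#' @param activation `"sigmoid"` for multi-label, `"softmax"` for
#'   single-label.
#' @param dropout dropout probability on input and hidden layers during
#'   training (default 0.5).
#' @param seed integer seed.
#' @return A `predictor_params` list of weight arrays plus architecture tags.
#' @export
predictor_init <- function(d, C, hidden = 128L,
                           combine = c("sum", "concat"),
                           activation = c("sigmoid", "softmax"),
                           dropout = 0.5, seed = 1L) {
  combine <- match.arg(combine)
  activation <- match.arg(activation)
  with_seed(seed, {
    p <- list(d = d, C = C, hidden = as.integer(hidden), combine = combine,
              activation = activation, dropout = dropout,
              W1 = xavier(d, hidden), b1 = numeric(hidden),
              u = as.numeric(xavier(d, 1L)), v = as.numeric(xavier(d, 1L)))
    if (combine == "sum") {
      p$W2 <- xavier(hidden, C); p$b2 <- numeric(C)
      p$W3 <- xavier(d, C); p$b3 <- numeric(C)
    } else {
      p$Wc <- xavier(d + hidden, C); p$bc <- numeric(C)
    }
    structure(p, class = "predictor_params")
  })
}

# Names of the numeric parameter arrays (the trainable set Phi).
param_fields <- function(params) {
  intersect(c("W1", "b1", "W2", "b2", "W3", "b3", "Wc", "bc", "u", "v"),
            names(params))
}

# Edge list (target i, source j) with self-loops, used by the attention
# branch's masked softmax. Computed once per graph and reusable.
attention_edges <- function(graph) {
  A <- methods::as(graph$adjacency, "TsparseMatrix")
  ei <- c(A@i + 1L, seq_len(graph$n_nodes))
  ej <- c(A@j + 1L, seq_len(graph$n_nodes))
  ord <- order(ei, ej)
  list(i = ei[ord], j = ej[ord])
}

lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

#' Attention + MLP forward pass
#'
#' Computes node label probabilities \eqn{Z \in [0,1]^{n \times C}} from
#' propagated features. The attention branch scores each neighbour pair with
#' additive attention \eqn{s_{ij} = \mathrm{LeakyReLU}(u^\top x_i + v^\top
#' x_j)}, softmax-normalized over the neighbourhood of i (self included), and
#' aggregates neighbour features; the MLP branch is a 2-layer ReLU network on
#' the node's own propagated features. Deterministic given `params` (dropout
#' is applied only when `training = TRUE`).
#'
#' @param X_bar propagated feature matrix (n x d).
#' @param graph the `sgraph` supplying the attention neighbourhoods.
#' @param params a `predictor_params`.
#' @param training apply dropout masks (requires `dropout_seed`).
#' @param dropout_seed seed for the dropout masks when `training`.
#' @param edges optional precomputed [attention_edges()] list.
#' @param return_cache also return intermediates for backpropagation.
#' @return Probability matrix `Z` (n x C), or, with `return_cache`, a list
#'   `(Z, logits, cache)`.
#' @export
att_mlp_forward <- function(X_bar, graph, params, training = FALSE,
                            dropout_seed = NULL, edges = NULL,
                            return_cache = FALSE) {
  X_bar <- as.matrix(X_bar)
  if (ncol(X_bar) != params$d) stop_validation("X_bar feature dimension mismatch")
  if (params$C != ncol(graph$labels)) stop_validation("params C mismatch with graph labels")
  n <- nrow(X_bar)
  edges <- edges %||% attention_edges(graph)

  Xd <- X_bar
  mask_in <- NULL
  if (training && params$dropout > 0) {
    mask_in <- with_seed(dropout_seed,
      matrix(stats::rbinom(n * params$d, 1L, 1 - params$dropout), n)) / (1 - params$dropout)
    Xd <- X_bar * mask_in
  }

  # MLP branch
  Z1 <- sweep(Xd %*% params$W1, 2, params$b1, `+`)
  H1 <- pmax(Z1, 0)
  Hd <- H1
  mask_h <- NULL
  if (training && params$dropout > 0) {
    mask_h <- with_seed(if (is.null(dropout_seed)) NULL else dropout_seed + 1L,
      matrix(stats::rbinom(length(H1), 1L, 1 - params$dropout), n)) / (1 - params$dropout)
    Hd <- H1 * mask_h
  }

  # attention branch
  ui <- as.numeric(Xd %*% params$u)
  vj <- as.numeric(Xd %*% params$v)
  pre <- ui[edges$i] + vj[edges$j]
  s <- lrelu(pre)
  gmax <- tapply_max(s, edges$i, n)  # per-neighbourhood max, for stable softmax
  es <- exp(s - gmax[edges$i])
  gsum <- as.numeric(rowsum(es, edges$i, reorder = TRUE))
  alpha <- es / gsum[edges$i]
  m <- rowsum(Xd[edges$j, , drop = FALSE] * alpha, edges$i, reorder = TRUE)

  if (params$combine == "sum") {
    logits <- sweep(Hd %*% params$W2, 2, params$b2, `+`) +
      sweep(m %*% params$W3, 2, params$b3, `+`)
  } else {
    R <- cbind(m, Hd)
    logits <- sweep(R %*% params$Wc, 2, params$bc, `+`)
  }
  dimnames(logits) <- NULL
  Z <- if (params$activation == "softmax") row_softmax(logits) else sigmoid(logits)
  if (!return_cache) return(Z)
  list(Z = Z, logits = logits,
       cache = list(Xd = Xd, mask_in = mask_in, Z1 = Z1, H1 = H1, Hd = Hd,
                    mask_h = mask_h, pre = pre, alpha = alpha, m = m,
                    edges = edges, n = n))
}

# per-group maximum (groups are 1..n, every group non-empty via self-loops)
tapply_max <- function(x, g, n) {
  out <- rep(-Inf, n)
  o <- order(g)
  gm <- vapply(split(x[o], g[o]), max, numeric(1))
  out[as.integer(names(gm))] <- gm
  out
}

# Backward pass: gradient of a scalar loss with dL/dlogits = G
# (n x C) with respect to every parameter array. Returns a named list
# mirroring param_fields().
att_mlp_backward <- function(G, params, cache) {
  ed <- cache$edges
  Xd <- cache$Xd
  grads <- list()
  if (params$combine == "sum") {
    grads$W2 <- crossprod(cache$Hd, G)
    grads$b2 <- colSums(G)
    dHd <- G %*% t(params$W2)
    grads$W3 <- crossprod(cache$m, G)
    grads$b3 <- colSums(G)
    dm <- G %*% t(params$W3)
  } else {
    R <- cbind(cache$m, cache$Hd)
    grads$Wc <- crossprod(R, G)
    grads$bc <- colSums(G)
    dR <- G %*% t(params$Wc)
    dm <- dR[, seq_len(params$d), drop = FALSE]
    dHd <- dR[, params$d + seq_len(params$hidden), drop = FALSE]
  }
  # MLP branch
  dH1 <- if (is.null(cache$mask_h)) dHd else dHd * cache$mask_h
  dZ1 <- dH1 * (cache$Z1 > 0)
  grads$W1 <- crossprod(Xd, dZ1)
  grads$b1 <- colSums(dZ1)
  # attention branch
  dalpha <- rowSums(dm[ed$i, , drop = FALSE] * Xd[ed$j, , drop = FALSE])
  cgrp <- as.numeric(rowsum(cache$alpha * dalpha, ed$i, reorder = TRUE))
  ds <- cache$alpha * (dalpha - cgrp[ed$i])
  dpre <- ds * lrelu_grad(cache$pre)
  grads$u <- as.numeric(crossprod(Xd[ed$i, , drop = FALSE], dpre))
  grads$v <- as.numeric(crossprod(Xd[ed$j, , drop = FALSE], dpre))
  grads
}

#' Sharpen a probability matrix
#'
#' Temperature transform \eqn{Z'_{ij} = Z_{ij}^{1/T} / \sum_c Z_{ic}^{1/T}}
#' lowering the entropy of each row distribution for `T < 1`; identity at
#' `T = 1`; approaches one-hot argmax as `T` tends to 0.
#'
#' @param Z matrix whose rows are probability distributions (entries >= 0,
#'   positive row sums).
#' @param T positive temperature.
#' @return Sharpened matrix; rows remain distributions.
#' @export
sharpen <- function(Z, T) {
  Z <- as.matrix(Z)
  if (length(T) != 1L || is.na(T) || T <= 0) stop_argument("T must be > 0")
  if (any(Z < 0)) stop_validation("Z must be non-negative")
  rs <- rowSums(Z)
  if (any(rs == 0)) stop_validation("Z has an all-zero row")
  # work in log space for numerical stability
  L <- log(pmax(Z, .Machine$double.xmin)) / T
  L[Z == 0] <- -Inf
  W <- exp(L - apply(L, 1L, max))
  W / rowSums(W)
}

#' Sharpen per-label Bernoulli probabilities
#'
#' Multi-label analogue of [sharpen()]: each entry's Bernoulli pair
#' `(p, 1 - p)` is sharpened independently,
#' \eqn{p' = p^{1/T} / (p^{1/T} + (1-p)^{1/T})}.
#'
#' @param P matrix of probabilities in `[0, 1]`.
#' @param T positive temperature.
#' @return Matrix of sharpened probabilities.
#' @export
sharpen_bernoulli <- function(P, T) {
  if (length(T) != 1L || is.na(T) || T <= 0) stop_argument("T must be > 0")
  P <- as.matrix(P)
  if (any(P < 0 | P > 1)) stop_validation("P must lie in [0, 1]")
  a <- P^(1 / T)
  b <- (1 - P)^(1 / T)
  a / (a + b)
}

#' Save / load predictor parameters as a flat text archive
#'
#' @param params a `predictor_params`.
#' @param path file path (RDS-free plain text, `dput` format).
#' @return `params_save` the path, invisibly; `params_load` the restored
#'   `predictor_params`.
#' @export
params_save <- function(params, path) {
  dput(unclass(params), file = path)
  invisible(path)
}

#' @rdname params_save
#' @export
params_load <- function(path) {
  structure(dget(path), class = "predictor_params")
}
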