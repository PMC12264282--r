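# Wasserstein-1 adversarial alignment of source and target feature
# distributions: a 1-Lipschitz critic (enforced by a gradient penalty)
# estimates the dual-form W1 between embedded source features and
# generator-transformed target features; the generator (an affine feature
# map initialized at identity) is trained to shrink it.

#' Exact empirical 1-D Wasserstein-1 distance (sorting oracle)
#'
#' For equal-sized one-dimensional samples the optimal coupling pairs sorted
#' values, so \eqn{W_1} is the mean absolute difference of the sorted
#' samples. Used as the independent oracle the adversarial critic is checked
#' against.
#'
#' @param xs,ys numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
wasserstein1_sorted_oracle <- function(xs, ys) {
  if (length(xs) != length(ys)) stop_argument("samples must have equal sizes")
  mean(abs(sort(xs) - sort(ys)))
}

#' Initialize a critic network
#'
#' One-hidden-layer tanh network \eqn{f(x) = w_2^\top \tanh(W_1 x + b_1) +
#' b_2}; small enough that its input gradient, and the gradient of the
#' Lipschitz penalty, are available in closed form.
#'
#' @param d input dimension.
#' @param hidden hidden width.
#' @param seed integer seed.
#' @return A `critic` parameter list.
#' @export
critic_init <- function(d, hidden = 32L, seed = 1L) {
  with_seed(seed, structure(
    list(W1 = xavier(d, hidden), b1 = numeric(hidden),
         w2 = as.numeric(xavier(hidden, 1L)), b2 = 0, d = d, hidden = hidden),
    class = "critic"))
}

critic_forward <- function(f, X) {
  A <- tanh(sweep(as.matrix(X) %*% f$W1, 2, f$b1, `+`))
  as.numeric(A %*% f$w2 + f$b2)
}

# per-sample input gradients dF/dx, rows of an m x d matrix
critic_input_grad <- function(f, X) {
  A <- tanh(sweep(as.matrix(X) %*% f$W1, 2, f$b1, `+`))
  Cc <- sweep(1 - A^2, 2, f$w2, `*`)
  Cc %*% t(f$W1)
}

#' Identity-initialized feature generator
#'
#' Affine target-feature transform \eqn{G(x) = W_g x + b_g} initialized at
#' the identity. `mode` restricts which parts are trainable: `"shift"`
#' (translation only, the default -- the most stable minimax at moderate
#' sample sizes), `"diag"` (per-coordinate scale + shift), `"affine"` (full
#' matrix).
#'
#' @param d feature dimension.
#' @param mode `"shift"`, `"diag"` or `"affine"`.
#' @return A `feature_generator` with `Wg = I`, `bg = 0` (so the initial map
#'   is the identity).
#' @export
generator_init <- function(d, mode = c("shift", "diag", "affine")) {
  mode <- match.arg(mode)
  structure(list(Wg = diag(d), bg = numeric(d), d = d, mode = mode),
            class = "feature_generator")
}

generator_apply <- function(G, X) {
  if (is.null(G)) return(as.matrix(X))
  sweep(as.matrix(X) %*% G$Wg, 2, G$bg, `+`)
}

#' Critic objective with Lipschitz gradient penalty
#'
#' \eqn{\mathbb{E}_{x \sim p_s}[f(x)] - \mathbb{E}_{x \sim p_t}[f(G(x))] -
#' \lambda\,\mathbb{E}_{\hat x}[(\lVert \nabla f(\hat x) \rVert - 1)^2]},
#' the penalized dual-form Wasserstein-1 surrogate; interpolates \eqn{\hat x}
#' lie on chords between source and transformed-target samples. The
#' unpenalized difference of means is attached as attribute `"raw"` and the
#' penalty as `"penalty"`.
#'
#' @param f a [critic_init()] parameter list.
#' @param source_batch,target_batch feature matrices (rows = samples).
#' @param G optional [generator_init()] transform applied to the target.
#' @param gp_lambda gradient-penalty weight.
#' @param seed seed for the interpolation coefficients.
#' @return Scalar objective (raw minus penalty), with attributes `raw` and
#'   `penalty`.
#' @export
critic_objective <- function(f, source_batch, target_batch, G = NULL,
                             gp_lambda = 10, seed = 1L) {
  Xs <- as.matrix(source_batch)
  Xt <- generator_apply(G, target_batch)
  if (nrow(Xs) == 0 || nrow(Xt) == 0) stop_argument("batches must be non-empty")
  raw <- mean(critic_forward(f, Xs)) - mean(critic_forward(f, Xt))
  m <- min(nrow(Xs), nrow(Xt))
  eps <- with_seed(seed, stats::runif(m))
  Xh <- eps * Xs[seq_len(m), , drop = FALSE] + (1 - eps) * Xt[seq_len(m), , drop = FALSE]
  gn <- sqrt(rowSums(critic_input_grad(f, Xh)^2))
  pen <- mean((gn - 1)^2)
  structure(raw - gp_lambda * pen, raw = raw, penalty = pen)
}

# analytic gradients of the penalized critic objective wrt critic params
critic_grads <- function(f, Xs, Xt, gp_lambda, seed) {
  grad_part <- function(X, sign) {
    A <- tanh(sweep(X %*% f$W1, 2, f$b1, `+`))
    Cc <- sweep(1 - A^2, 2, f$w2, `*`)
    list(w2 = sign * colMeans(A),
         W1 = sign * crossprod(X, Cc) / nrow(X),
         b1 = sign * colMeans(Cc))
  }
  gs <- grad_part(Xs, 1)
  gt <- grad_part(Xt, -1)
  g <- list(W1 = gs$W1 + gt$W1, b1 = gs$b1 + gt$b1, w2 = gs$w2 + gt$w2)
  # gradient penalty: P = mean((|grad_x f| - 1)^2) over interpolates
  m <- min(nrow(Xs), nrow(Xt))
  eps <- with_seed(seed, stats::runif(m))
  Xh <- eps * Xs[seq_len(m), , drop = FALSE] + (1 - eps) * Xt[seq_len(m), , drop = FALSE]
  A <- tanh(sweep(Xh %*% f$W1, 2, f$b1, `+`))
  Cc <- sweep(1 - A^2, 2, f$w2, `*`)
  Gm <- Cc %*% t(f$W1)                       # per-sample input gradients
  gn <- pmax(sqrt(rowSums(Gm^2)), 1e-12)
  Q <- (2 * (gn - 1) / gn) * Gm / m          # dP/dg per sample
  Tm <- Q %*% f$W1
  dz <- Tm * sweep(-2 * A * (1 - A^2), 2, f$w2, `*`)
  pen <- list(W1 = crossprod(Q, Cc) + crossprod(Xh, dz),
              b1 = colSums(dz),
              w2 = colSums(Tm * (1 - A^2)))
  list(W1 = g$W1 - gp_lambda * pen$W1,
       b1 = g$b1 - gp_lambda * pen$b1,
       w2 = g$w2 - gp_lambda * pen$w2)
}

# Orient the critic to the positive mode of the dual: f and -f are both
# 1-Lipschitz and attain opposite signs of the mean difference, so pick the
# representative with E_s f - E_t f >= 0 (negate w2/b2 otherwise).
orient_critic <- function(f, Xs, Xt) {
  raw <- mean(critic_forward(f, Xs)) - mean(critic_forward(f, Xt))
  if (raw < 0) {
    f$w2 <- -f$w2
    f$b2 <- -f$b2
  }
  f
}

# minimal Adam over a named list of arrays
list_adam_init <- function(p, fields) {
  list(m = lapply(p[fields], function(x) x * 0),
       v = lapply(p[fields], function(x) x * 0), t = 0L)
}

list_adam_step <- function(p, g, st, lr, maximize = FALSE) {
  st$t <- st$t + 1L
  for (f in names(st$m)) {
    gf <- if (maximize) g[[f]] else -g[[f]]
    st$m[[f]] <- 0.9 * st$m[[f]] + 0.1 * gf
    st$v[[f]] <- 0.999 * st$v[[f]] + 0.001 * gf^2
    p[[f]] <- p[[f]] + lr * (st$m[[f]] / (1 - 0.9^st$t)) /
      (sqrt(st$v[[f]] / (1 - 0.999^st$t)) + 1e-8)
  }
  list(p = p, st = st)
}

#' Train the critic to estimate W1 between two samples
#'
#' Gradient ascent (Adam) on the penalized dual objective with the generator
#' held fixed; returns the trained critic and the trajectory of raw
#' objective values.
#'
#' @inheritParams critic_objective
#' @param steps ascent steps.
#' @param lr learning rate.
#' @param hidden critic hidden width.
#' @param seed integer seed.
#' @return List with `critic` and `history` (raw objective per step).
#' @export
train_critic <- function(source_batch, target_batch, G = NULL, steps = 600L,
                         lr = 0.03, hidden = 32L, gp_lambda = 30, seed = 1L) {
  Xs <- as.matrix(source_batch)
  Xt <- generator_apply(G, target_batch)
  f <- critic_init(ncol(Xs), hidden, seed)
  st <- list_adam_init(f, c("W1", "b1", "w2"))
  hist <- numeric(steps)
  for (k in seq_len(steps)) {
    g <- critic_grads(f, Xs, Xt, gp_lambda, seed = seed + k)
    upd <- list_adam_step(f, g, st, lr, maximize = TRUE)
    f <- upd$p; st <- upd$st
    hist[k] <- mean(critic_forward(f, Xs)) - mean(critic_forward(f, Xt))
  }
  f <- orient_critic(f, Xs, Xt)
  list(critic = f, history = hist)
}

#' Dual-form W1 estimate from a trained critic
#'
#' Evaluates \eqn{|\,\mathbb{E}_{x_s} f(x) - \mathbb{E}_{x_t} f(x)\,|} on
#' (held-out) samples; the absolute value is the dual estimate because `-f`
#' belongs to the same 1-Lipschitz class.
#'
#' @param f a trained critic.
#' @param xs,ys sample matrices (or vectors).
#' @return Non-negative scalar lower bound (up to optimization slack) on W1.
#' @export
critic_w1_estimate <- function(f, xs, ys) {
  abs(mean(critic_forward(f, as.matrix(xs))) - mean(critic_forward(f, as.matrix(ys))))
}

#' Adversarial domain adaptation of embedded features
#'
#' Alternating minimax on embedded (propagated) features: `critic_steps`
#' critic ascent updates per generator update, the generator descending
#' \eqn{\alpha_{da} \cdot} the alignment term. The task model is left frozen;
#' the learned generator maps target embeddings into the source feature
#' distribution, so source-trained heads transfer. Aborts to the last good
#' state on divergence.
#'
#' @param source_emb,target_emb embedded feature matrices (same width).
#' @param alpha_da alignment loss weight (scales the generator step).
#' @param critic_steps critic updates per generator update.
#' @param gen_steps generator updates.
#' @param pretrain_steps critic warm-up updates before the generator moves.
#' @param lr_critic,lr_gen learning rates (critic: Adam; generator: plain
#'   gradient steps, whose size is bounded by the critic's ~unit gradient
#'   norm).
#' @param hidden critic hidden width.
#' @param gp_lambda gradient-penalty weight.
#' @param seed integer seed.
#' @return An `sg_adaptation`: list with `G` (the affine map), `critic`,
#'   and `history` (data.frame: step, critic raw objective, penalty).
#' @export
adapt <- function(source_emb, target_emb, alpha_da = 0.1, critic_steps = 5L,
                  gen_steps = 100L, pretrain_steps = 200L, lr_critic = 0.03,
                  lr_gen = 1, hidden = 32L, gp_lambda = 30, seed = 1L,
                  generator = c("shift", "diag", "affine")) {
  generator <- match.arg(generator)
  Xs <- as.matrix(source_emb)
  Xt0 <- as.matrix(target_emb)
  if (ncol(Xs) != ncol(Xt0)) stop_validation("source and target must share feature width")
  d <- ncol(Xs)
  f <- critic_init(d, hidden, seed)
  G <- generator_init(d, generator)
  st_f <- list_adam_init(f, c("W1", "b1", "w2"))
  for (k in seq_len(pretrain_steps)) {
    gf <- critic_grads(f, Xs, Xt0, gp_lambda, seed = seed + k)
    upd <- list_adam_step(f, gf, st_f, lr_critic, maximize = TRUE)
    f <- upd$p; st_f <- upd$st
  }
  hist <- vector("list", gen_steps)
  last_good <- list(G = G, critic = f)
  for (step in seq_len(gen_steps)) {
    Xt <- generator_apply(G, Xt0)
    for (k in seq_len(critic_steps)) {
      gf <- critic_grads(f, Xs, Xt, gp_lambda, seed = seed + 97L * step + k)
      upd <- list_adam_step(f, gf, st_f, lr_critic, maximize = TRUE)
      f <- upd$p; st_f <- upd$st
    }
    f <- orient_critic(f, Xs, Xt)
    # generator: move G(x) up the critic's gradient, shrinking E_s f - E_t f(G)
    Gr <- critic_input_grad(f, Xt) / nrow(Xt)
    G$bg <- G$bg + lr_gen * alpha_da * colSums(Gr)
    if (G$mode == "diag") {
      diag(G$Wg) <- diag(G$Wg) + lr_gen * alpha_da * colSums(Gr * Xt0)
    } else if (G$mode == "affine") {
      G$Wg <- G$Wg + lr_gen * alpha_da * crossprod(Xt0, Gr)
    }
    obj <- critic_objective(f, Xs, generator_apply(G, Xt0), NULL, gp_lambda,
                            seed = seed + step)
    if (!is.finite(obj)) {
      warning("adaptation diverged at step ", step, "; returning last good state")
      return(structure(c(last_good,
                         list(history = do.call(rbind, hist[seq_len(step - 1L)]))),
                       class = "sg_adaptation"))
    }
    last_good <- list(G = G, critic = f)
    hist[[step]] <- data.frame(step = step, critic_raw = attr(obj, "raw"),
                               penalty = attr(obj, "penalty"))
  }
  structure(list(G = G, critic = f, history = do.call(rbind, hist)),
            class = "sg_adaptation")
}

#' Predict on a target-domain graph through a learned adaptation
#'
#' Propagates the target graph's features, maps them through the adaptation
#' generator, and applies the source-trained head.
#'
#' @param model a fitted `semigraph`.
#' @param target_graph target-domain `sgraph`.
#' @param adaptation an `sg_adaptation` from [adapt()] (or `NULL` for the
#'   unadapted baseline).
#' @return Probability matrix on the target graph.
#' @export
predict_adapted <- function(model, target_graph, adaptation = NULL) {
  op_t <- mixed_order_operator(normalize_adjacency(target_graph, model$config$strategy),
                               model$config$K)
  Xb <- propagate(op_t, target_graph$features)
  if (!is.null(adaptation)) Xb <- generator_apply(adaptation$G, Xb)
  att_mlp_forward(Xb, target_graph, model$params, training = FALSE)
}
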