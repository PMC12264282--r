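# Reinforcement-learning construction of the label dependency graph. A
# logistic policy decides, pair by pair, whether a label-graph edge should be
# present; trajectories are scored by a cheap downstream proxy (label-score
# smoothing over the candidate graph) plus a sparsity penalty, and the policy
# is improved with the REINFORCE estimator with a mean-return baseline.

#' Initialize a label-graph policy
#'
#' Affine-sigmoid policy over 5 state features: (empirical pair
#' co-occurrence, degree of each endpoint in the current label graph /C,
#' edge density |E|/C^2, taxonomy-depth difference if provided).
#'
#' @param w numeric length-5 weight vector (default zeros).
#' @param b scalar bias (default 0).
#' @return A `label_policy` list.
#' @export
label_policy <- function(w = numeric(5), b = 0) {
  structure(list(w = as.numeric(w), b = as.numeric(b)), class = "label_policy")
}

# empirical label co-occurrence, scaled to [0, 1] off the diagonal
empirical_cooccurrence <- function(Y) {
  Y <- as.matrix(Y)
  co <- crossprod(Y)
  diag(co) <- 0
  m <- max(co)
  if (m > 0) co <- co / m
  co
}

label_state_features <- function(G, pair, cooc, depth_of = NULL) {
  C <- nrow(G)
  i <- pair[1]; j <- pair[2]
  c(cooc = cooc[i, j],
    deg_i = sum(G[i, ]) / C,
    deg_j = sum(G[j, ]) / C,
    density = sum(G) / (2 * C^2),
    depth_diff = if (is.null(depth_of)) 0 else abs(depth_of[i] - depth_of[j]))
}

#' Edge probability under the label-graph policy
#'
#' \eqn{\pi_\theta(a \mid s) = \sigma(w^\top s + b)}: the probability that
#' the candidate edge is made present.
#'
#' @param state numeric feature vector of the candidate pair (see
#'   `label_state_features`), or a list with element `features`.
#' @param theta a [label_policy()].
#' @return Probability in `(0, 1)`.
#' @export
policy_prob <- function(state, theta) {
  f <- if (is.list(state)) state$features else as.numeric(state)
  sigmoid(sum(theta$w[seq_along(f)] * f) + theta$b)
}

#' Discounted returns-to-go
#'
#' \eqn{G_t = \sum_{t' \ge t} \gamma^{t'-t} r_{t'}}.
#'
#' @param rewards numeric reward sequence.
#' @param gamma discount in `[0, 1]`.
#' @return Numeric vector of the same length.
#' @export
returns_to_go <- function(rewards, gamma) {
  if (gamma < 0 || gamma > 1) stop_argument("gamma must lie in [0, 1]")
  Rev <- rev(rewards)
  out <- numeric(length(rewards))
  acc <- 0
  for (k in seq_along(Rev)) {
    acc <- Rev[k] + gamma * acc
    out[k] <- acc
  }
  rev(out)
}

#' Step reward for a label-graph edit
#'
#' \eqn{r_t = \Delta(\text{downstream score}) - \beta \, \Delta |E|}: the
#' change in the downstream evaluation minus a sparsity penalty on the change
#' in edge count.
#'
#' @param score_before,score_after downstream scores around the edit.
#' @param edges_before,edges_after edge counts around the edit.
#' @param beta_sparsity penalty per added edge.
#' @return Finite scalar reward.
#' @export
reward <- function(score_before, score_after, edges_before, edges_after,
                   beta_sparsity = 0.01) {
  r <- (score_after - score_before) - beta_sparsity * (edges_after - edges_before)
  if (!is.finite(r)) stop("downstream evaluation produced a non-finite score")
  r
}

#' Default downstream proxy for label-graph quality
#'
#' A frozen lightweight coding model: one mixed-order propagation of the node
#' features plus a ridge linear head fitted once on the train mask gives base
#' label scores `Z0`; a candidate label graph `G` is scored by smoothing
#' `Z0` over the row-normalized `G + I` and measuring micro AUC on the
#' validation mask. Edges linking genuinely co-occurring labels raise the
#' score; spurious cross-branch edges dilute it.
#'
#' @param graph an `sgraph` with train and val masks.
#' @param K propagation order of the frozen model.
#' @param ridge ridge penalty of the linear head.
#' @return A function `f(G)` mapping a C x C 0/1 matrix to a scalar score.
#' @export
label_graph_proxy <- function(graph, K = 2L, ridge = 1) {
  op <- mixed_order_operator(normalize_adjacency(graph, "M2"), K)
  Xb <- propagate(op, graph$features)
  tr <- graph$masks$train
  va <- if (length(graph$masks$val)) graph$masks$val else tr
  Xtr <- Xb[tr, , drop = FALSE]
  W <- solve(crossprod(Xtr) + ridge * diag(ncol(Xb)),
             crossprod(Xtr, graph$labels[tr, , drop = FALSE]))
  Z0 <- Xb %*% W
  Yv <- graph$labels[va, , drop = FALSE]
  function(G) {
    P <- (G + diag(nrow(G)))
    P <- P / rowSums(P)
    Zg <- Z0[va, , drop = FALSE] %*% t(P)
    auc(as.vector(Zg), as.vector(Yv))
  }
}

#' Held-out co-occurrence downstream scorer
#'
#' Scores a candidate label graph by how well its edges track label
#' co-occurrence measured on a held-out node set: \eqn{\sum_{(i,j) \in G}
#' (\tilde c_{ij} - \bar c)}, where \eqn{\tilde c} is the max-normalized
#' co-occurrence count over `mask` nodes and \eqn{\bar c} its off-diagonal
#' mean. Edges between genuinely co-occurring labels score positive, edges
#' across unrelated branches negative. A direct structural-quality measure,
#' complementary to the prediction-based [label_graph_proxy()].
#'
#' @param Y binary node-label matrix.
#' @param mask node indices the co-occurrence is measured on (e.g. the
#'   validation mask); default all nodes.
#' @return A function `f(G) -> score`.
#' @export
label_cooccurrence_score <- function(Y, mask = NULL) {
  Y <- as.matrix(Y)
  mask <- mask %||% seq_len(nrow(Y))
  co <- crossprod(Y[mask, , drop = FALSE])
  diag(co) <- 0
  if (max(co) > 0) co <- co / max(co)
  c0 <- mean(co[upper.tri(co)])
  function(G) {
    ut <- upper.tri(G)
    sum((co[ut] - c0) * G[ut])
  }
}

#' Run one label-graph construction episode
#'
#' Starting from an empty label graph, samples `horizon` uniformly random
#' candidate pairs; for each, the policy's sigmoid probability decides
#' (Bernoulli draw) whether the edge is present after the step, the graph
#' transition itself being deterministic given the action. Rewards are the
#' downstream-score delta minus the sparsity penalty.
#'
#' @param Y binary node-label matrix (supplies the co-occurrence feature).
#' @param theta a [label_policy()].
#' @param downstream_eval function `f(G) -> score`; `NULL` scores every graph
#'   0 (pure sparsity shaping).
#' @param horizon number of steps (default `2 C`).
#' @param gamma discount factor.
#' @param beta_sparsity sparsity penalty.
#' @param seed integer seed.
#' @param depth_of optional per-label taxonomy depth.
#' @param deterministic take the modal action (p > 0.5) instead of sampling.
#' @return A `label_trajectory`: list with `features` (T x 5), `actions`,
#'   `probs`, `rewards`, `returns`, `gamma`, and the final graph `G`.
#' @export
run_label_episode <- function(Y, theta, downstream_eval = NULL,
                              horizon = NULL, gamma = 0.9,
                              beta_sparsity = 0.01, seed = 1L,
                              depth_of = NULL, deterministic = FALSE) {
  C <- ncol(Y)
  horizon <- horizon %||% (2L * C)
  cooc <- empirical_cooccurrence(Y)
  evalG <- downstream_eval %||% function(G) 0
  with_seed(seed, {
    G <- matrix(0L, C, C)
    score <- evalG(G)
    feats <- matrix(0, horizon, 5L)
    actions <- integer(horizon); probs <- numeric(horizon); rewards <- numeric(horizon)
    for (t in seq_len(horizon)) {
      pair <- sample.int(C, 2L)
      f <- label_state_features(G, pair, cooc, depth_of)
      p <- policy_prob(f, theta)
      a <- if (deterministic) as.integer(p > 0.5) else stats::rbinom(1L, 1L, p)
      e_before <- sum(G) / 2
      G[pair[1], pair[2]] <- G[pair[2], pair[1]] <- a
      e_after <- sum(G) / 2
      new_score <- evalG(G)
      rewards[t] <- reward(score, new_score, e_before, e_after, beta_sparsity)
      score <- new_score
      feats[t, ] <- f; actions[t] <- a; probs[t] <- p
    }
    structure(list(features = feats, actions = actions, probs = probs,
                   rewards = rewards, returns = returns_to_go(rewards, gamma),
                   gamma = gamma, G = G),
              class = "label_trajectory")
  })
}

#' REINFORCE policy-gradient estimate
#'
#' Mean over trajectories of \eqn{\hat g = \sum_t \nabla_\theta \log
#' \pi_\theta(a_t \mid s_t) \sum_{t' \ge t} \gamma^{t'-t} r_{t'}}. For the
#' affine-sigmoid policy, \eqn{\nabla_\theta \log \pi = (a_t - p_t)\,[s_t,
#' 1]}. An optional mean-return baseline is subtracted per step index; it
#' does not bias the estimator.
#'
#' @param trajectories list of `label_trajectory` objects sampled under
#'   `theta`.
#' @param theta the current [label_policy()] (probabilities are recomputed
#'   under it).
#' @param baseline subtract the across-trajectory mean return at each step.
#' @return Numeric gradient vector of length 6 (`w` then `b`), named.
#' @export
reinforce_gradient_estimate <- function(trajectories, theta, baseline = FALSE) {
  if (length(trajectories) == 0) stop_argument("empty trajectory set")
  returns <- lapply(trajectories, `[[`, "returns")
  base <- 0
  if (baseline) {
    maxT <- max(lengths(returns))
    padded <- vapply(returns, function(r) c(r, rep(NA_real_, maxT - length(r))), numeric(maxT))
    base <- rowMeans(matrix(padded, nrow = maxT), na.rm = TRUE)
  }
  g <- numeric(length(theta$w) + 1L)
  for (tr in trajectories) {
    p <- sigmoid(as.numeric(tr$features %*% theta$w) + theta$b)
    adv <- tr$returns - (if (baseline) base[seq_along(tr$returns)] else 0)
    coefs <- (tr$actions - p) * adv
    g <- g + c(colSums(tr$features * coefs), sum(coefs))
  }
  g <- g / length(trajectories)
  names(g) <- c(paste0("w", seq_along(theta$w)), "b")
  g
}

#' Train the label-graph policy by policy-gradient ascent
#'
#' @param Y binary node-label matrix.
#' @param downstream_eval downstream scorer (see [label_graph_proxy()]).
#' @param iterations ascent iterations.
#' @param episodes_per_iter trajectories per gradient estimate.
#' @param lr ascent step size.
#' @inheritParams run_label_episode
#' @return List with the trained `theta` and per-iteration mean returns.
#' @export
train_label_policy <- function(Y, downstream_eval = NULL, iterations = 30L,
                               episodes_per_iter = 8L, lr = 0.5,
                               horizon = NULL, gamma = 0.9,
                               beta_sparsity = 0.01, seed = 1L,
                               depth_of = NULL) {
  theta <- label_policy()
  hist <- numeric(iterations)
  for (it in seq_len(iterations)) {
    trajs <- lapply(seq_len(episodes_per_iter), function(e)
      run_label_episode(Y, theta, downstream_eval, horizon, gamma,
                        beta_sparsity, seed = seed + 1000L * it + e,
                        depth_of = depth_of))
    g <- reinforce_gradient_estimate(trajs, theta, baseline = TRUE)
    theta$w <- theta$w + lr * g[seq_along(theta$w)]
    theta$b <- theta$b + lr * g[length(g)]
    hist[it] <- mean(vapply(trajs, function(tr) sum(tr$rewards), numeric(1)))
  }
  list(theta = theta, mean_return = hist)
}

#' Generate a label graph with a (trained) policy
#'
#' Sequential edge decisions over `horizon` uniformly random candidate
#' pairs. With `deterministic = TRUE`, each visited pair takes its modal
#' action; a `sweep = TRUE` pass instead visits every label pair exactly
#' once in index order (useful for reading out the learned structure).
#'
#' @param Y binary node-label matrix.
#' @param theta a [label_policy()].
#' @param horizon steps for the sampled construction.
#' @param seed integer seed.
#' @param deterministic take modal actions.
#' @param sweep decide every pair once, deterministically.
#' @param depth_of optional per-label taxonomy depth.
#' @return C x C symmetric 0/1 label-graph adjacency.
#' @export
generate_label_graph <- function(Y, theta, horizon = NULL, seed = 1L,
                                 deterministic = FALSE, sweep = FALSE,
                                 depth_of = NULL) {
  C <- ncol(Y)
  cooc <- empirical_cooccurrence(Y)
  if (sweep) {
    G <- matrix(0L, C, C)
    for (i in seq_len(C - 1)) for (j in (i + 1):C) {
      p <- policy_prob(label_state_features(G, c(i, j), cooc, depth_of), theta)
      G[i, j] <- G[j, i] <- as.integer(p > 0.5)
    }
    return(G)
  }
  run_label_episode(Y, theta, downstream_eval = NULL, horizon = horizon,
                    seed = seed, depth_of = depth_of,
                    deterministic = deterministic)$G
}
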