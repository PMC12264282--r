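# Consistency-regularized semi-supervised training: supervised loss on the
# labeled nodes averaged over S stochastic augmentations, plus a consistency
# penalty tying every augmentation's predictions to a sharpened mean target
# over ALL nodes. Optimized full-batch with Adam.

#' Training configuration
#'
#' All tunable hyperparameters with their defaults. Unknown names are
#' rejected.
#'
#' @param ... name-value overrides of the defaults: `strategy` ("M2"), `K`
#'   (4), `S` (4), `delta` (0.2), `dn_mode` ("per_augmentation",
#'   "once_per_epoch" or "none"), `perturb` ("dropnode"/"dropout"), `T` (0.5),
#'   `lambda` (1.0), `alpha` (0.1, residual mixing), `epsilon` (0.01),
#'   `depth` (2), `hidden` (128), `dropout` (0.5), `combine` ("sum"),
#'   `activation` ("sigmoid"), `lr` (1e-3), `weight_decay` (0), `epochs`
#'   (100), `patience` (10), `batch` (64, accepted for interface parity;
#'   training is full-batch at node level), `gamma` (0.9), `horizon` (NA =
#'   2C), `beta_sparsity` (0.01), `alpha_da` (0.1), `critic_steps` (5),
#'   `seed` (1), `sharpen_target` (TRUE), `verbose` (FALSE).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    strategy = "M2", K = 4L, S = 4L, delta = 0.2,
    dn_mode = "per_augmentation", perturb = "dropnode",
    T = 0.5, lambda = 1.0, alpha = 0.1, epsilon = 0.01, depth = 2L,
    hidden = 128L, dropout = 0.5, combine = "sum", activation = "sigmoid",
    lr = 1e-3, weight_decay = 0, epochs = 100L, patience = 10L, batch = 64L,
    gamma = 0.9, horizon = NA_integer_, beta_sparsity = 0.01,
    alpha_da = 0.1, critic_steps = 5L, seed = 1L,
    sharpen_target = TRUE, verbose = FALSE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop_argument("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Supervised loss over augmentations
#'
#' \eqn{L_{sup} = -\frac{1}{S}\sum_s \sum_{i \in train} Y_i^\top \log
#' Z_i^{(s)}} (probabilities floor-clipped at 1e-12). With
#' `negative_terms = TRUE` the complementary \eqn{-(1-Y)^\top \log(1-Z)} term
#' is added, giving the full Bernoulli cross-entropy used by the sigmoid
#' multi-label training path.
#'
#' @param Y binary label matrix (n x C).
#' @param Z_list list of S prediction matrices.
#' @param train_mask integer node indices; must be non-empty.
#' @param negative_terms include the (1-Y) log(1-Z) terms.
#' @return Non-negative scalar.
#' @export
supervised_loss <- function(Y, Z_list, train_mask, negative_terms = FALSE) {
  if (length(train_mask) == 0) stop_validation("empty train mask")
  Y <- as.matrix(Y)[train_mask, , drop = FALSE]
  tot <- 0
  for (Z in Z_list) {
    Zi <- pmin(pmax(as.matrix(Z)[train_mask, , drop = FALSE], 1e-12), 1)
    tot <- tot - sum(Y * log(Zi))
    if (negative_terms) tot <- tot - sum((1 - Y) * log(pmax(1 - Zi, 1e-12)))
  }
  tot / length(Z_list)
}

#' Consistency loss across augmentations
#'
#' \eqn{L_{con} = \frac{1}{S}\sum_s \sum_i \lVert \bar Z_i - Z_i^{(s)}
#' \rVert^2} over all nodes (labeled and unlabeled), where \eqn{\bar Z} is
#' the mean prediction (or a supplied, e.g. sharpened, target).
#'
#' @param Z_list list of S prediction matrices.
#' @param target optional alignment target; default: elementwise mean of
#'   `Z_list`.
#' @return Non-negative scalar; exactly 0 when S = 1 and no target is given.
#' @export
consistency_loss <- function(Z_list, target = NULL) {
  S <- length(Z_list)
  target <- target %||% Reduce(`+`, Z_list) / S
  sum(vapply(Z_list, function(Z) sum((target - Z)^2), numeric(1))) / S
}

# Adam optimizer state over a named list of arrays
adam_init <- function(params) {
  fields <- param_fields(params)
  list(m = lapply(params[fields], function(p) p * 0),
       v = lapply(params[fields], function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(params, grads, state, lr, weight_decay = 0) {
  state$t <- state$t + 1L
  for (f in names(state$m)) {
    g <- grads[[f]]
    if (is.null(g)) next
    if (weight_decay > 0 && !startsWith(f, "b")) g <- g + weight_decay * params[[f]]
    state$m[[f]] <- state$beta1 * state$m[[f]] + (1 - state$beta1) * g
    state$v[[f]] <- state$beta2 * state$v[[f]] + (1 - state$beta2) * g^2
    mhat <- state$m[[f]] / (1 - state$beta1^state$t)
    vhat <- state$v[[f]] / (1 - state$beta2^state$t)
    params[[f]] <- params[[f]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

# gradient of loss wrt logits through the output activation, given dL/dZ
activation_backward <- function(G, Z, activation) {
  if (activation == "softmax") Z * (G - rowSums(G * Z)) else G * Z * (1 - Z)
}

predict_inference <- function(graph, op, params, edges = NULL) {
  Xb <- propagate(op, graph$features)
  att_mlp_forward(Xb, graph, params, training = FALSE, edges = edges)
}

val_metric <- function(Z, graph, mask) {
  if (length(mask) == 0) return(NA_real_)
  Y <- graph$labels[mask, , drop = FALSE]
  P <- binarize_predictions(Z[mask, , drop = FALSE],
                            attr(Z, "activation") %||% "sigmoid")
  f1_scores(P, Y)$micro
}

binarize_predictions <- function(Z, activation) {
  if (activation == "softmax") {
    P <- matrix(0L, nrow(Z), ncol(Z))
    P[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))] <- 1L
    P
  } else {
    (Z >= 0.5) * 1L
  }
}

#' Train the consistency-regularized node classifier
#'
#' Full-batch Adam minimization of \eqn{L = L_{sup} + \lambda L_{con}}. Each
#' epoch draws `S` fresh DropNode augmentations, runs the attention+MLP head
#' on each, and backpropagates the supervised loss (labeled nodes) plus the
#' consistency loss against the stop-gradient sharpened mean prediction (all
#' nodes). Early stopping tracks validation micro-F1 with the configured
#' patience; the best-validation parameters are returned. Deterministic
#' given `config$seed`.
#'
#' @param graph an `sgraph` with a non-empty train mask.
#' @param op a `propagation_operator` with `K` set (built from `config` if
#'   `NULL`).
#' @param params initial `predictor_params` (initialized from `config` if
#'   `NULL`).
#' @param config a [run_config()].
#' @return A `train_result`: list with `params` (best), `history` (per-epoch
#'   data.frame of `L_sup`, `L_con`, `L_total`, `val_metric`), `best_epoch`,
#'   `op`, `config`.
#' @export
train <- function(graph, op = NULL, params = NULL, config = run_config()) {
  stopifnot(inherits(graph, "sgraph"))
  if (length(graph$masks$train) == 0) stop_validation("empty train mask")
  op <- op %||% mixed_order_operator(
    normalize_adjacency(graph, config$strategy), config$K)
  params <- params %||% predictor_init(
    d = ncol(graph$features), C = ncol(graph$labels), hidden = config$hidden,
    combine = config$combine, activation = config$activation,
    dropout = config$dropout, seed = config$seed)
  edges <- attention_edges(graph)
  train_mask <- graph$masks$train
  Y <- graph$labels
  negative_terms <- params$activation == "sigmoid"
  opt <- adam_init(params)
  best <- list(metric = -Inf, params = params, epoch = 0L)
  hist <- vector("list", config$epochs)
  wait <- 0L
  S_eff <- if (config$dn_mode == "none") 1L else config$S

  for (epoch in seq_len(config$epochs)) {
    ep_seed <- config$seed + 1000L * epoch
    mode <- if (config$dn_mode == "none") "none" else config$perturb
    batch <- if (config$dn_mode == "once_per_epoch") {
      # one shared perturbation reused for every augmentation
      b1 <- random_propagate(graph, op, S = 1L, delta = config$delta,
                             mode = mode, seed = ep_seed)
      b1$X_bar_list <- rep(b1$X_bar_list, config$S)
      b1$S <- config$S
      b1
    } else {
      random_propagate(graph, op, S = S_eff, delta = config$delta,
                       mode = mode, seed = ep_seed)
    }

    fw <- lapply(seq_len(batch$S), function(s)
      att_mlp_forward(batch$X_bar_list[[s]], graph, params, training = TRUE,
                      dropout_seed = ep_seed + 7L * s, edges = edges,
                      return_cache = TRUE))
    Z_list <- lapply(fw, `[[`, "Z")
    S <- batch$S

    L_sup <- supervised_loss(Y, Z_list, train_mask, negative_terms = negative_terms)
    Zbar <- Reduce(`+`, Z_list) / S
    target <- if (!config$sharpen_target) Zbar
      else if (params$activation == "softmax") sharpen(Zbar, config$T)
      else sharpen_bernoulli(Zbar, config$T)
    # a single augmentation carries no disagreement to penalize
    L_con <- if (S == 1L) 0 else consistency_loss(Z_list, target = target)
    L_total <- L_sup + config$lambda * L_con
    if (!is.finite(L_total))
      stop("training diverged: non-finite loss at epoch ", epoch)

    grads <- NULL
    for (s in seq_len(S)) {
      Z <- Z_list[[s]]
      # cross-entropy through softmax (one-hot Y) and Bernoulli cross-entropy
      # through sigmoid both reduce to (Z - Y) on the labeled rows
      # gradients are per-node normalized (mean over labeled nodes for the
      # supervised term, mean over all nodes for consistency) so that the
      # lambda = 1 default balances the two terms regardless of how few
      # nodes are labeled; reported losses keep the summed form
      Glog_sup <- matrix(0, nrow(Z), ncol(Z))
      Glog_sup[train_mask, ] <- (Z[train_mask, , drop = FALSE] -
                                 Y[train_mask, , drop = FALSE]) / (S * length(train_mask))
      Glog <- Glog_sup
      if (S > 1L) {
        Gcon <- (2 / (S * nrow(Z))) * (Z - target) * config$lambda
        Glog <- Glog + activation_backward(Gcon, Z, params$activation)
      }
      g <- att_mlp_backward(Glog, params, fw[[s]]$cache)
      grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
    }
    upd <- adam_update(params, grads, opt, config$lr, config$weight_decay)
    params <- upd$params
    opt <- upd$state

    Zinf <- predict_inference(graph, op, params, edges)
    attr(Zinf, "activation") <- params$activation
    vm <- val_metric(Zinf, graph, graph$masks$val)
    hist[[epoch]] <- data.frame(epoch = epoch, L_sup = L_sup, L_con = L_con,
                                L_total = L_total, val_metric = vm)
    if (config$verbose)
      message(sprintf("epoch %3d  L_sup %.4f  L_con %.4f  val %.4f",
                      epoch, L_sup, L_con, vm))
    if (!is.na(vm) && vm > best$metric) {
      best <- list(metric = vm, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.na(vm) && wait >= config$patience) break
    }
  }
  if (is.infinite(best$metric)) best <- list(metric = NA_real_, params = params,
                                             epoch = length(Filter(Negate(is.null), hist)))
  structure(list(params = best$params, history = do.call(rbind, Filter(Negate(is.null), hist)),
                 best_epoch = best$epoch, best_val = best$metric,
                 op = op, config = config),
            class = "train_result")
}

#' Perturbed-loss expansion check
#'
#' In the binary single-layer setting (\eqn{z = \sigma(\bar A X W)} with a
#' single weight column), compares the Monte-Carlo expectation of the
#' DropNode-perturbed supervised loss against its second-order expansion
#' \eqn{L_{orig} + R^c(W)} with
#' \eqn{R^c(W) = \frac{1}{2}\sum_i z_i(1-z_i)\,\mathrm{Var}_i}.
#'
#' @param graph an `sgraph` whose first label column supplies the binary
#'   target.
#' @param op `propagation_operator` with `K` set.
#' @param W numeric weight vector.
#' @param delta DropNode probability.
#' @param n_draws Monte-Carlo sample size.
#' @param mask node set the losses sum over (default: all nodes).
#' @param seed integer seed.
#' @return List with `empirical` (MC mean of the perturbed loss), `approx`
#'   (`L_orig + R_c`), `L_orig`, `R_c` and `rel_gap`.
#' @export
theoretical_loss_gap <- function(graph, op, W, delta, n_draws = 50000L,
                                 mask = NULL, seed = 1L) {
  y <- graph$labels[, 1]
  mask <- mask %||% seq_len(graph$n_nodes)
  X <- graph$features
  Abar <- a_bar_dense(op)
  xw <- as.numeric(X %*% as.numeric(W))
  z <- sigmoid(as.numeric(Abar %*% xw))
  bce <- function(zv) -sum(y[mask] * log(pmax(zv[mask, , drop = FALSE], 1e-12)) +
                           (1 - y[mask]) * log(pmax(1 - zv[mask, , drop = FALSE], 1e-12))) /
                      ncol(zv)
  L_orig <- -sum(y[mask] * log(pmax(z[mask], 1e-12)) +
                 (1 - y[mask]) * log(pmax(1 - z[mask], 1e-12)))
  if (delta == 0) {
    return(list(empirical = L_orig, approx = L_orig, L_orig = L_orig,
                R_c = 0, rel_gap = 0))
  }
  emp <- with_seed(seed, {
    M <- matrix(stats::rbinom(length(xw) * n_draws, 1L, 1 - delta),
                nrow = length(xw)) / (1 - delta)
    Zt <- sigmoid(Abar %*% (M * xw))
    bce(as.matrix(Zt))
  })
  v <- analytic_variance_dropnode(op, X, W, delta)
  R_c <- 0.5 * sum((z * (1 - z) * v)[mask])
  approx <- L_orig + R_c
  list(empirical = emp, approx = approx, L_orig = L_orig, R_c = R_c,
       rel_gap = abs(emp - approx) / abs(emp))
}
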