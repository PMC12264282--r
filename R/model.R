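#' Fit a robust semi-supervised node classifier
#'
#' Top-level fitting interface. Builds the mixed-order propagation operator,
#' initializes the attention+MLP head, and runs consistency-regularized
#' training with DropNode augmentation (see [train()] for the procedure).
#' Returns a classed model object with the usual `print`, `summary`,
#' `predict`, `coef`, `plot` and `residuals` methods.
#'
#' @param graph an [sgraph()] with non-empty train (and ideally validation)
#'   masks.
#' @param ... hyperparameter overrides forwarded to [run_config()], e.g.
#'   `S = 4`, `delta = 0.2`, `lambda = 1`, `activation = "softmax"`.
#' @return An object of class `semigraph`.
#' @examples
#' \donttest{
#' g <- generate_multilabel_graph(synth_config(n_nodes = 120, n_labels = 5,
#'   taxonomy_depth = 2, feature_dim = 8, seed = 1))
#' fit <- semigraph(g, epochs = 5, hidden = 16, S = 2)
#' print(fit)
#' head(predict(fit))
#' }
#' @export
semigraph <- function(graph, ...) {
  config <- run_config(...)
  res <- train(graph, config = config)
  structure(list(params = res$params, op = res$op, history = res$history,
                 best_epoch = res$best_epoch, best_val = res$best_val,
                 config = config, graph = graph,
                 call = match.call()),
            class = "semigraph")
}

#' @export
print.semigraph <- function(x, ...) {
  cat("Semi-supervised graph node classifier\n")
  cat(sprintf("  nodes %d, labels %d, strategy %s, K = %d, S = %d, delta = %.2f, lambda = %.2f\n",
              x$graph$n_nodes, ncol(x$graph$labels), x$config$strategy,
              x$config$K, x$config$S, x$config$delta, x$config$lambda))
  cat(sprintf("  trained %d epochs (best epoch %d, val micro-F1 %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val))
  invisible(x)
}

#' @export
summary.semigraph <- function(object, ...) {
  Z <- predict(object)
  out <- list(model = object,
              test_metrics = if (length(object$graph$masks$test))
                metrics_report(Z[object$graph$masks$test, , drop = FALSE],
                               object$graph$labels[object$graph$masks$test, , drop = FALSE])
              else NULL,
              history_tail = utils::tail(object$history, 3))
  class(out) <- "summary.semigraph"
  out
}

#' @export
print.summary.semigraph <- function(x, ...) {
  print(x$model)
  cat("\nFinal epochs:\n")
  print(x$history_tail, row.names = FALSE)
  if (!is.null(x$test_metrics)) {
    cat("\nTest-mask metrics:\n")
    print(x$test_metrics)
  }
  invisible(x)
}

#' Predict node label probabilities
#'
#' Inference uses the unperturbed features (`delta = 0`): one deterministic
#' mixed-order propagation followed by the trained head.
#'
#' @param object a fitted `semigraph` model.
#' @param newgraph optional `sgraph` to predict on (defaults to the training
#'   graph); must share the feature and label dimensionality.
#' @param type `"prob"` for the probability matrix, `"class"` for binarized
#'   predictions (argmax for softmax, 0.5 threshold for sigmoid).
#' @param ... unused.
#' @return n x C matrix of probabilities or 0/1 predictions.
#' @export
predict.semigraph <- function(object, newgraph = NULL, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  g <- newgraph %||% object$graph
  op <- if (is.null(newgraph)) object$op else
    mixed_order_operator(normalize_adjacency(g, object$config$strategy), object$config$K)
  Z <- predict_inference(g, op, object$params)
  if (type == "class") binarize_predictions(Z, object$params$activation) else Z
}

#' @export
coef.semigraph <- function(object, ...) {
  p <- object$params
  p[param_fields(p)]
}

#' @export
residuals.semigraph <- function(object, ...) {
  Z <- predict(object)
  (object$graph$labels - Z)[object$graph$masks$train, , drop = FALSE]
}

#' Plot training history
#'
#' Loss curves (supervised, consistency, total) and validation micro-F1 by
#' epoch.
#'
#' @param x a fitted `semigraph`.
#' @param ... passed to `matplot`.
#' @export
plot.semigraph <- function(x, ...) {
  h <- x$history
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  graphics::matplot(h$epoch, cbind(h$L_sup, h$L_con, h$L_total), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L_sup", "L_con", "L_total"), col = 1:3, lty = 1, bty = "n")
  graphics::plot(h$epoch, h$val_metric, type = "l", xlab = "epoch",
                 ylab = "validation micro-F1")
  invisible(x)
}
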