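# Synthetic data: homophilous multi-label graphs with a planted hierarchical
# label taxonomy (ICD-like co-occurrence), domain-shifted twins, and
# random-edge attacks. Everything is deterministic given the config seed.

#' Synthetic benchmark configuration
#'
#' @param n_nodes number of nodes.
#' @param n_labels number of labels C.
#' @param taxonomy_depth depth of the planted label tree (must not exceed
#'   `log2(C) + 2`).
#' @param labels_per_node mean number of labels per node (>= 1).
#' @param homophily homophily strength h in `[0, 1]`: 0 makes edges
#'   independent of labels, values near 1 concentrate edges on label-sharing
#'   pairs.
#' @param feature_dim feature dimension d.
#' @param feature_noise per-coordinate Gaussian noise sd on node features.
#' @param labeled_fraction fraction of nodes in the train mask (the same
#'   fraction is used for validation; the rest is test).
#' @param avg_degree mean node degree; the edge count is exactly
#'   `round(n_nodes * avg_degree / 2)`.
#' @param single_label if `TRUE` each node carries exactly one label
#'   (one-hot rows), the mode used for accuracy-based ablations.
#' @param feature_mode `"gaussian"` (label-keyed Gaussian mixture) or
#'   `"counts"` (sparse Poisson bag-of-words-like counts).
#' @param mean_shift,var_scale,edge_noise domain-shift parameters consumed by
#'   [domain_shift()].
#' @param seed integer seed; fully determines the generated data.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_nodes = 500L, n_labels = 20L, taxonomy_depth = 3L,
                         labels_per_node = 2.5, homophily = 0.8,
                         feature_dim = 64L, feature_noise = 0.5,
                         labeled_fraction = 0.1, avg_degree = 10,
                         single_label = FALSE,
                         feature_mode = c("gaussian", "counts"),
                         mean_shift = 0.5, var_scale = 1, edge_noise = 0.1,
                         seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  cfg <- as.list(environment())
  for (r in c("homophily", "labeled_fraction", "edge_noise"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop_argument(r, " must lie in [0, 1]")
  if (labeled_fraction == 0) stop_argument("labeled_fraction must be positive")
  structure(cfg, class = "synth_config")
}

#' Planted hierarchical label taxonomy
#'
#' Builds a random rooted tree over `C` labels with the requested depth and a
#' co-occurrence matrix whose entries decay geometrically with tree distance
#' (`decay^dist`, unit diagonal): labels close in the hierarchy co-occur
#' often, distant branches rarely -- the structure diagnostic-code sets
#' exhibit.
#'
#' @param C number of labels (>= 2).
#' @param depth tree depth (levels below the root); error if it exceeds
#'   `log2(C) + 2`.
#' @param seed integer seed.
#' @param decay geometric decay of co-occurrence with tree distance.
#' @return A `label_taxonomy`: list with `parent` (NA for the root), `level`,
#'   `edges` (parent-child matrix), `dist` (tree distances) and
#'   `cooccurrence`.
#' @export
generate_taxonomy <- function(C, depth, seed = 1L, decay = 0.5) {
  if (C < 2) stop_argument("C must be >= 2")
  if (depth < 1 || depth > log2(C) + 2) stop_argument("depth must lie in 1..log2(C)+2")
  if (depth > C - 1) stop_argument("depth cannot exceed C - 1")
  with_seed(seed, {
    level <- integer(C)
    level[1] <- 0L
    # spread the remaining labels over levels 1..depth, each level non-empty
    lv <- sort(c(seq_len(depth), sample(seq_len(depth), C - 1 - depth, replace = TRUE)))
    level[-1] <- lv
    parent <- rep(NA_integer_, C)
    for (l in seq_len(depth)) {
      children <- which(level == l)
      pool <- which(level == l - 1L)
      parent[children] <- if (length(pool) == 1L) pool else
        sample(pool, length(children), replace = TRUE)
    }
    edges <- cbind(parent = parent[-1], child = seq_len(C)[-1])
    D <- tree_distances(parent, C)
    co <- decay^D
    diag(co) <- 1
    structure(list(parent = parent, level = level, edges = edges,
                   dist = D, cooccurrence = co, C = C, decay = decay),
              class = "label_taxonomy")
  })
}

# all-pairs distances on a tree given parent pointers (C is small)
tree_distances <- function(parent, C) {
  A <- matrix(Inf, C, C)
  diag(A) <- 0
  for (c in seq_len(C)) if (!is.na(parent[c])) A[c, parent[c]] <- A[parent[c], c] <- 1
  for (k in seq_len(C)) {
    A <- pmin(A, outer(A[, k], A[k, ], `+`))
  }
  A
}

#' Generate a homophilous multi-label graph
#'
#' Samples, in order: a label taxonomy; per-node label sets (a uniform
#' primary label plus co-occurring secondaries drawn proportionally to the
#' taxonomy co-occurrence, targeting `labels_per_node` on average); exactly
#' `round(n * avg_degree / 2)` edges drawn without replacement with weights
#' `(1 - h) + 9 h` for label-sharing pairs and `(1 - h)` otherwise (h = 0
#' gives uniform, label-independent edges); label-keyed Gaussian (or Poisson
#' count) features; and disjoint train/val/test masks.
#'
#' @param config a [synth_config()].
#' @return An `sgraph` with attributes `taxonomy`, `config` and `primary`
#'   (the per-node primary label).
#' @export
generate_multilabel_graph <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_nodes; C <- config$n_labels; d <- config$feature_dim
  tax <- generate_taxonomy(C, config$taxonomy_depth, seed = config$seed)
  with_seed(config$seed + 1L, {
    primary <- sample.int(C, n, replace = TRUE)
    Y <- matrix(0L, n, C)
    Y[cbind(seq_len(n), primary)] <- 1L
    if (!config$single_label && config$labels_per_node > 1) {
      extra <- config$labels_per_node - 1
      for (i in seq_len(n)) {
        w <- tax$cooccurrence[primary[i], ]
        w[primary[i]] <- 0
        q <- pmin(1, extra * w / sum(w))
        Y[i, ] <- pmax(Y[i, ], stats::rbinom(C, 1L, q))
      }
    }
    # edges: exact count, weighted without replacement; the label-overlap
    # indicator is computed in blocks to keep memory flat in n
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    share <- integer(nrow(pairs))
    for (beg in seq(1L, nrow(pairs), by = 200000L)) {
      idx <- beg:min(beg + 199999L, nrow(pairs))
      share[idx] <- as.integer(rowSums(Y[pairs[idx, 1], , drop = FALSE] *
                                       Y[pairs[idx, 2], , drop = FALSE]) > 0)
    }
    h <- config$homophily
    wgt <- (1 - h) + 9 * h * share
    n_edges <- round(n * config$avg_degree / 2)
    if (n_edges > nrow(pairs)) stop_argument("avg_degree too large for n")
    sel <- sample.int(nrow(pairs), n_edges, prob = wgt)
    A <- Matrix::sparseMatrix(i = pairs[sel, 1], j = pairs[sel, 2], x = 1,
                              dims = c(n, n), symmetric = TRUE)
    A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
    # features
    M <- matrix(stats::rnorm(C * d), C, d) / sqrt(d)  # label prototype means
    base <- (Y %*% M) / pmax(rowSums(Y), 1)
    X <- if (config$feature_mode == "gaussian") {
      base + matrix(stats::rnorm(n * d, sd = config$feature_noise), n, d)
    } else {
      matrix(stats::rpois(n * d, lambda = pmax(exp(base), 1e-8)), n, d)
    }
    # masks
    perm <- sample.int(n)
    n_lab <- max(1L, round(config$labeled_fraction * n))
    masks <- list(train = perm[seq_len(n_lab)],
                  val = perm[n_lab + seq_len(min(n_lab, n - n_lab))],
                  test = perm[-seq_len(min(2L * n_lab, n))])
    g <- sgraph(A, X, Y, masks)
    attr(g, "taxonomy") <- tax
    attr(g, "config") <- config
    attr(g, "primary") <- primary
    g
  })
}

edge_pairs <- function(graph) {
  A <- methods::as(Matrix::triu(graph$adjacency), "TsparseMatrix")
  cbind(A@i + 1L, A@j + 1L)
}

replace_adjacency <- function(graph, pairs) {
  A <- Matrix::sparseMatrix(i = pairs[, 1], j = pairs[, 2], x = 1,
                            dims = c(graph$n_nodes, graph$n_nodes),
                            symmetric = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  g <- sgraph(A, graph$features, graph$labels, graph$masks, graph$label_names)
  for (a in c("taxonomy", "config", "primary")) attr(g, a) <- attr(graph, a)
  g
}

#' Domain-shifted twin of a graph
#'
#' Produces a target-domain copy: features shifted by `mean_shift`
#' (scalar or length-d vector) and rescaled by `sqrt(var_scale)`, and exactly
#' `round(edge_noise * |E|)` edges rewired (removed and replaced by fresh
#' random non-edges). Labels and masks are preserved.
#'
#' @param graph an `sgraph`.
#' @param mean_shift additive feature shift (scalar or length-d).
#' @param var_scale multiplicative feature variance scale.
#' @param edge_noise fraction of edges to rewire, in `[0, 1]`.
#' @param seed integer seed.
#' @return The shifted `sgraph`.
#' @export
domain_shift <- function(graph, mean_shift = 0.5, var_scale = 1,
                         edge_noise = 0.1, seed = 1L) {
  stopifnot(inherits(graph, "sgraph"))
  X <- sweep(graph$features * sqrt(var_scale), 2,
             rep_len(mean_shift, ncol(graph$features)), `+`)
  pairs <- edge_pairs(graph)
  k <- round(edge_noise * nrow(pairs))
  if (k > 0) {
    with_seed(seed, {
      drop_idx <- sample.int(nrow(pairs), k)
      kept <- pairs[-drop_idx, , drop = FALSE]
      new_pairs <- sample_non_edges(graph$n_nodes, rbind(kept), k)
      pairs <- rbind(kept, new_pairs)
    })
  }
  g <- replace_adjacency(graph, pairs)
  g$features <- X
  g
}

# draw k distinct non-self pairs not already present in `pairs`
sample_non_edges <- function(n, pairs, k) {
  existing <- pairs[, 1] + n * pairs[, 2]
  total_non_edges <- n * (n - 1) / 2 - nrow(pairs)
  if (k > total_non_edges) stop_argument("not enough non-edges to add ", k, " edges")
  out <- matrix(0L, 0L, 2L)
  while (nrow(out) < k) {
    i <- sample.int(n, 2L * k, replace = TRUE)
    j <- sample.int(n, 2L * k, replace = TRUE)
    lo <- pmin(i, j); hi <- pmax(i, j)
    ok <- lo < hi
    key <- lo + n * hi
    ok <- ok & !(key %in% existing) & !duplicated(key)
    cand <- cbind(lo[ok], hi[ok])
    if (nrow(cand)) {
      take <- utils::head(cand, k - nrow(out))
      out <- rbind(out, take)
      existing <- c(existing, take[, 1] + n * take[, 2])
    }
  }
  out
}

#' Random-edge adversarial attack
#'
#' Adds exactly `round(p * |E|)` fake edges drawn uniformly among the
#' non-edges (no duplicates, no self-loops); the original edges are left
#' untouched.
#'
#' @param graph an `sgraph`.
#' @param p attack rate in `[0, 1]`, relative to the current edge count.
#' @param seed integer seed.
#' @return The attacked `sgraph`.
#' @export
random_edge_attack <- function(graph, p, seed = 1L) {
  stopifnot(inherits(graph, "sgraph"))
  if (p < 0 || p > 1) stop_argument("p must lie in [0, 1]")
  pairs <- edge_pairs(graph)
  k <- round(p * nrow(pairs))
  if (k == 0) return(graph)
  new_pairs <- with_seed(seed, sample_non_edges(graph$n_nodes, pairs, k))
  replace_adjacency(graph, rbind(pairs, new_pairs))
}
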