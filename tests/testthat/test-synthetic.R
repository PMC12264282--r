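test_that("taxonomy generation plants a tree with distance-decaying co-occurrence", {
  # two labels, depth 1: single parent-child pair
  t2 <- generate_taxonomy(2, 1, seed = 1)
  expect_equal(t2$parent, c(NA, 1L))
  expect_equal(unname(t2$cooccurrence[1, 2]), t2$decay)
  # determinism
  expect_identical(generate_taxonomy(12, 3, seed = 5),
                   generate_taxonomy(12, 3, seed = 5))
  # depth limits
  expect_error(generate_taxonomy(8, 6, seed = 1), class = "semigraph_argument_error")
  expect_error(generate_taxonomy(1, 1, seed = 1), class = "semigraph_argument_error")
  # co-occurrence decreases strictly with tree distance
  tx <- generate_taxonomy(15, 3, seed = 7)
  ut <- upper.tri(tx$dist)
  expect_true(all(diff(tapply(tx$cooccurrence[ut], tx$dist[ut], unique)) < 0))
  expect_true(isSymmetric(tx$cooccurrence))
  expect_equal(diag(tx$cooccurrence), rep(1, 15))
  # every non-root has a parent one level up
  expect_true(all(tx$level[tx$edges[, "child"]] ==
                  tx$level[tx$edges[, "parent"]] + 1))
})

test_that("generated graphs match the requested sizes exactly and reproduce", {
  cfg <- synth_config(n_nodes = 120, n_labels = 6, taxonomy_depth = 2,
                      feature_dim = 5, avg_degree = 6, seed = 9)
  g <- generate_multilabel_graph(cfg)
  expect_equal(g$n_nodes, 120)
  expect_equal(Matrix::nnzero(g$adjacency) / 2, round(120 * 6 / 2))
  expect_equal(dim(g$features), c(120, 5))
  expect_equal(dim(g$labels), c(120, 6))
  expect_equal(length(g$masks$train), 12)
  # disjoint masks cover distinct nodes
  expect_equal(anyDuplicated(unlist(g$masks)), 0)
  # byte-identical regeneration
  g2 <- generate_multilabel_graph(cfg)
  expect_identical(g$features, g2$features)
  expect_identical(g$labels, g2$labels)
  expect_identical(as.matrix(g$adjacency), as.matrix(g2$adjacency))
  # multi-label rows: at least one label each, several on average
  expect_true(all(rowSums(g$labels) >= 1))
  expect_gt(mean(rowSums(g$labels)), 1.5)
  expect_error(synth_config(labeled_fraction = 0),
               class = "semigraph_argument_error")
})

test_that("homophily strength controls label assortativity of edges", {
  homo_frac <- function(g) {
    ep <- semigraph:::edge_pairs(g)
    mean(rowSums(g$labels[ep[, 1], , drop = FALSE] *
                 g$labels[ep[, 2], , drop = FALSE]) > 0)
  }
  gh <- generate_multilabel_graph(synth_config(homophily = 0.9, seed = 17))
  expect_gt(homo_frac(gh), 0.7)
  # h = 0: edge placement independent of label sharing (two-proportion test
  # not significant at alpha = 0.01)
  g0 <- generate_multilabel_graph(synth_config(n_nodes = 2000, homophily = 0,
                                               avg_degree = 6, seed = 18))
  ep <- semigraph:::edge_pairs(g0)
  edge_share <- rowSums(g0$labels[ep[, 1], ] * g0$labels[ep[, 2], ]) > 0
  set.seed(19)
  i <- sample.int(2000, 20000, replace = TRUE)
  j <- sample.int(2000, 20000, replace = TRUE)
  keep <- i < j
  rnd_share <- rowSums(g0$labels[i[keep], ] * g0$labels[j[keep], ]) > 0
  p <- prop.test(c(sum(edge_share), sum(rnd_share)),
                 c(length(edge_share), length(rnd_share)))$p.value
  expect_gt(p, 0.01)
})

test_that("domain shift moves features and rewires the stated edge fraction", {
  g <- small_bench(20, n = 100)
  # zero shift: identical graph
  g0 <- domain_shift(g, mean_shift = 0, var_scale = 1, edge_noise = 0, seed = 1)
  expect_equal(g0$features, g$features)
  expect_identical(as.matrix(g0$adjacency), as.matrix(g$adjacency))
  # mean shift moves the empirical feature mean by the shift
  gs <- domain_shift(g, mean_shift = 0.7, var_scale = 1, edge_noise = 0, seed = 1)
  expect_equal(colMeans(gs$features) - colMeans(g$features),
               rep(0.7, ncol(g$features)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # labels and masks preserved; edge count preserved under rewiring
  gr <- domain_shift(g, mean_shift = 0, edge_noise = 0.1, seed = 2)
  expect_identical(gr$labels, g$labels)
  expect_identical(gr$masks, g$masks)
  E0 <- semigraph:::edge_pairs(g)
  E1 <- semigraph:::edge_pairs(gr)
  expect_equal(nrow(E1), nrow(E0))
  key <- function(E) paste(E[, 1], E[, 2])
  changed <- length(setdiff(key(E0), key(E1)))
  expect_equal(changed, round(0.1 * nrow(E0)))
})

test_that("random edge attack adds exactly the requested fake edges", {
  g <- small_bench(21, n = 100)
  expect_identical(as.matrix(random_edge_attack(g, 0, seed = 1)$adjacency),
                   as.matrix(g$adjacency))
  E0 <- semigraph:::edge_pairs(g)
  ga <- random_edge_attack(g, 0.1, seed = 3)
  E1 <- semigraph:::edge_pairs(ga)
  expect_equal(nrow(E1) - nrow(E0), round(0.1 * nrow(E0)))
  key <- function(E) paste(E[, 1], E[, 2])
  # original edges untouched; added edges disjoint from the original set
  expect_true(all(key(E0) %in% key(E1)))
  expect_equal(length(intersect(setdiff(key(E1), key(E0)), key(E0))), 0)
  expect_true(all(Matrix::diag(ga$adjacency) == 0))
  expect_error(random_edge_attack(g, 1.5, seed = 1),
               class = "semigraph_argument_error")
  # requesting more edges than non-edges available fails loudly
  K4 <- 1 - diag(4)
  gfull <- sgraph(methods::as(Matrix::Matrix(K4, sparse = TRUE), "CsparseMatrix"),
                  matrix(0, 4, 1), matrix(1, 4, 1))
  expect_error(random_edge_attack(gfull, 1, seed = 1),
               class = "semigraph_argument_error")
})

test_that("the Poisson count feature mode produces non-negative integers", {
  g <- generate_multilabel_graph(synth_config(n_nodes = 60, n_labels = 5,
    taxonomy_depth = 2, feature_dim = 6, feature_mode = "counts", seed = 22))
  expect_true(all(g$features >= 0))
  expect_true(all(g$features == round(g$features)))
})
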