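# Plain-text on-disk formats: Matrix Market sparse adjacency (or 0-based
# edge-list TSV), TSV feature/label matrices, a TSV mask table and a YAML
# manifest. Node ids in files are 0-based; in-memory R objects are 1-based.

#' Write a graph dataset to a directory
#'
#' Writes `adjacency.mtx`, `features.tsv`, `labels.tsv`, `masks.tsv`
#' (columns `node` 0-based and `split`), `taxonomy.tsv` (parent-child label
#' edges, 0-based, when a planted taxonomy is attached) and `manifest.yaml`
#' (generator config and seed when available).
#'
#' @param graph an `sgraph`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "sgraph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(graph$adjacency, file.path(dir, "adjacency.mtx"))
  utils::write.table(graph$features, file.path(dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(graph$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  mk <- do.call(rbind, lapply(names(graph$masks), function(nm) {
    if (length(graph$masks[[nm]]) == 0) return(NULL)
    data.frame(node = graph$masks[[nm]] - 1L, split = nm)
  }))
  utils::write.table(mk, file.path(dir, "masks.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE)
  tax <- attr(graph, "taxonomy")
  if (!is.null(tax))
    utils::write.table(tax$edges - 1L, file.path(dir, "taxonomy.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  cfg <- attr(graph, "config")
  manifest <- list(n_nodes = graph$n_nodes,
                   n_labels = ncol(graph$labels),
                   feature_dim = ncol(graph$features))
  if (!is.null(cfg)) manifest$config <- unclass(cfg)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

read_tsv_matrix <- function(path) {
  out <- tryCatch(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)),
                  error = function(e) stop_validation("malformed TSV ", path, ": ",
                                                      conditionMessage(e)))
  if (!is.numeric(out)) {
    bad <- which(apply(out, 1, function(r) any(is.na(suppressWarnings(as.numeric(r))))))[1]
    stop_validation("malformed TSV ", path, ": non-numeric value at line ", bad)
  }
  out
}

# read an adjacency from .mtx (explicit zeros pruned) or a 0-based 2-column
# edge-list TSV (symmetrized, deduplicated)
read_adjacency <- function(path, n_hint = NULL) {
  if (grepl("\\.mtx$", path)) {
    A <- Matrix::readMM(path)
    A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
    A <- Matrix::drop0(A)
    A@x[] <- 1
    return((A + Matrix::t(A)) > 0)
  }
  el <- utils::read.table(path, sep = "\t", header = FALSE)
  if (ncol(el) < 2) stop_validation("edge list ", path, " must have two columns")
  for (ln in seq_len(nrow(el)))
    if (any(is.na(suppressWarnings(as.integer(el[ln, 1:2])))))
      stop_validation("malformed edge list ", path, " at line ", ln)
  i <- as.integer(el[, 1]) + 1L
  j <- as.integer(el[, 2]) + 1L
  n <- n_hint %||% max(i, j)
  keep <- i != j
  lo <- pmin(i, j)[keep]; hi <- pmax(i, j)[keep]
  key <- !duplicated(paste(lo, hi))
  Matrix::sparseMatrix(i = c(lo[key], hi[key]), j = c(hi[key], lo[key]), x = 1,
                       dims = c(n, n))
}

#' Load a graph dataset from files
#'
#' @param paths named list/vector with entries `adjacency` (`.mtx` or
#'   edge-list `.tsv`), `features`, `labels` and optionally `masks`; or a
#'   directory written by [write_graph()].
#' @return A validated `sgraph` (adjacency symmetrized, explicit zeros
#'   pruned, masks checked disjoint).
#' @export
load_graph <- function(paths) {
  if (is.character(paths) && length(paths) == 1L) {
    if (!dir.exists(paths)) stop_validation("no such dataset directory: ", paths)
    paths <- list(adjacency = file.path(paths, "adjacency.mtx"),
                  features = file.path(paths, "features.tsv"),
                  labels = file.path(paths, "labels.tsv"),
                  masks = file.path(paths, "masks.tsv"))
  }
  for (nm in c("adjacency", "features", "labels"))
    if (!file.exists(paths[[nm]])) stop_validation("missing file: ", paths[[nm]])
  X <- read_tsv_matrix(paths$features)
  Y <- read_tsv_matrix(paths$labels)
  A <- read_adjacency(paths$adjacency, n_hint = nrow(X))
  A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  if (nrow(A) != nrow(X))
    stop_validation(paths$adjacency, ": adjacency has ", nrow(A),
                    " nodes but ", paths$features, " has ", nrow(X), " rows")
  if (nrow(Y) != nrow(X))
    stop_validation(paths$labels, ": label rows (", nrow(Y),
                    ") do not match feature rows (", nrow(X), ")")
  masks <- list(train = integer(), val = integer(), test = integer())
  if (!is.null(paths$masks) && file.exists(paths$masks)) {
    mk <- utils::read.table(paths$masks, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    for (ln in seq_len(nrow(mk))) {
      if (is.na(suppressWarnings(as.integer(mk$node[ln]))) ||
          !mk$split[ln] %in% c("train", "val", "test"))
        stop_validation("malformed mask file ", paths$masks, " at line ", ln + 1L)
    }
    for (nm in c("train", "val", "test"))
      masks[[nm]] <- as.integer(mk$node[mk$split == nm]) + 1L
  }
  sgraph(A, X, Y, masks)
}
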