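# Internal helpers: seeded RNG scoping, validation, numerics.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers never perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_validation <- function(...) {
  stop(structure(class = c("semigraph_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_argument <- function(...) {
  stop(structure(class = c("semigraph_argument_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

# Xavier-uniform init, deterministic given the surrounding seeded scope.
xavier <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

as_dense <- function(M) {
  if (inherits(M, "Matrix")) as.matrix(M) else M
}
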