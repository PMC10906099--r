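# Run-scoped RNG: every stochastic operation takes an explicit seed and
# restores the caller's random state on exit, so there is no global state.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  expr <- if (is.null(old)) {
    quote(rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}

# Pairwise squared Euclidean distances between rows of x and rows of y.
cross_dist2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# Indices of the k nearest rows of `ref` for each row of `query`
# (exact, Euclidean). Returns a query x k index matrix.
knn_index <- function(ref, query, k) {
  if (k > nrow(ref)) stop("k (", k, ") exceeds the reference size (",
                          nrow(ref), ").")
  d2 <- cross_dist2(query, ref)
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce any counts-like matrix to a general sparse dgCMatrix.
as_sparse_counts <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    methods::as(methods::as(methods::as(m, "CsparseMatrix"),
                            "generalMatrix"), "dMatrix")
  } else {
    Matrix::Matrix(as.matrix(m), sparse = TRUE)
  }
}
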