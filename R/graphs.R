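#' Sparsify a similarity view to its k-nearest-neighbour graph
#'
#' Row i of the returned graph keeps the similarities to the `k1` most
#' similar other entities (self excluded) and zeroes the rest; kept values
#' are unchanged.  Ties are broken by ascending entity index so graphs are
#' deterministic.  The result is generally asymmetric: j being among i's
#' neighbours does not make i one of j's.
#'
#' @param view A [similarity_view()] (or square numeric matrix).
#' @param k1 Neighbourhood size, `0 < k1 < n`.
#' @return Matrix of class `neighbor_graph` carrying `k1`, `kind`, `axis`
#'   attributes.
#' @export
knn_sparsify <- function(view, k1) {
  if (length(k1) != 1 || k1 <= 0 || k1 != round(k1)) {
    stop("`k1` must be a positive integer.", call. = FALSE)
  }
  a <- unclass(view)
  n <- nrow(a)
  if (k1 >= n) {
    stop("`k1` must be smaller than the number of entities.", call. = FALSE)
  }
  out <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    s <- a[i, ]
    s[i] <- -Inf                      # self excluded
    keep <- order(-s)[seq_len(k1)]    # stable order: ties -> smaller index
    out[i, keep] <- a[i, keep]
  }
  structure(out, k1 = as.integer(k1),
            kind = attr(view, "kind"), axis = attr(view, "axis"),
            class = c("neighbor_graph", "matrix", "array"))
}

#' Graph Laplacian of an asymmetric neighbour graph
#'
#' For a kNN-sparsified similarity graph A~ the Laplacian is
#' `L = (D + Dt) - (A~ + t(A~))`, where D holds row sums (out-degrees) and
#' Dt column sums (in-degrees) of A~.  Its quadratic form
#' `tr(U' L U) = sum_{i,mu} A~(i,mu) ||u_i - u_mu||^2` penalizes embedding
#' differences between graph neighbours.
#'
#' @param graph A [knn_sparsify()] result (or non-negative square matrix
#'   with zero diagonal).
#' @return List of class `laplacian_set` with elements `L` (matrix),
#'   `d_out`, `d_in` (degree vectors) and the originating `graph`.
#' @export
build_laplacian <- function(graph) {
  a <- unclass(graph)
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop("`graph` must be a square matrix.", call. = FALSE)
  }
  if (min(a) < 0) {
    stop("Neighbour graph weights must be non-negative.", call. = FALSE)
  }
  d_out <- rowSums(a)
  d_in <- colSums(a)
  L <- diag(d_out + d_in, nrow(a)) - (a + t(a))
  dimnames(L) <- dimnames(a)
  structure(list(L = L, d_out = d_out, d_in = d_in, graph = a),
            class = "laplacian_set")
}

#' @export
print.laplacian_set <- function(x, ...) {
  cat(sprintf("<laplacian_set> %d nodes, %d directed edges\n",
              nrow(x$L), sum(x$graph > 0)))
  invisible(x)
}
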