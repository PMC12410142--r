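#' Build the spatial k-nearest-neighbor graph
#'
#' Connects every spot to its `k` nearest other spots by Euclidean distance
#' (k = 3 by default, matching the near-hexagonal spacing of array-based
#' platforms, where interior spots have three equidistant immediate
#' neighbors). The directed k-NN edge set is symmetrized by union, so a row
#' can end up with more than `k` neighbors. Ties at the k-th distance are
#' broken toward the lower spot index, which makes the graph deterministic on
#' regular lattices.
#'
#' @param coords Numeric matrix of spot positions (n x 2), finite entries.
#' @param k Number of nearest neighbors per spot (default 3).
#' @return An object of class `spot_graph`: list with `adjacency` (sparse
#'   binary symmetric, zero diagonal), `norm_adjacency` (symmetric-normalized
#'   self-looped adjacency, see [normalize_adjacency()]), `neighbor_lists`
#'   (per-spot integer vectors), and `k`.
#' @examples
#' g <- build_knn_graph(cbind(c(0, 1, 2), c(0, 0, 0)), k = 1)
#' g$neighbor_lists
#' @export
build_knn_graph <- function(coords, k = 3) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (n <= k) stop("need more spots than k (n = ", n, ", k = ", k, ")")

  # chunked distance computation keeps memory bounded for large slides
  sq <- rowSums(coords^2)
  chunk <- max(1L, min(n, as.integer(2e7 / n)))
  nb_mat <- matrix(0L, n, k)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * coords[idx, , drop = FALSE] %*% t(coords)
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]
      di[i] <- Inf
      # ties at the k-th distance: lower index wins (stable order on index)
      nb_mat[i, ] <- order(di, seq_len(n))[seq_len(k)]
    }
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nb_mat)), x = 1, dims = c(n, n))
  A <- methods::as((A + Matrix::t(A)) > 0, "dMatrix") * 1  # union symmetrization
  A <- methods::as(A, "generalMatrix")
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  trip <- Matrix::summary(A)
  nb_list <- unname(split(as.integer(trip$j), factor(trip$i, levels = seq_len(n))))
  structure(list(adjacency = A, norm_adjacency = normalize_adjacency(A),
                 neighbor_lists = nb_list, k = as.integer(k)),
            class = "spot_graph")
}

#' @export
print.spot_graph <- function(x, ...) {
  cat(sprintf("spot_graph: %d spots, %d undirected edges (k = %d)\n",
              nrow(x$adjacency), Matrix::nnzero(x$adjacency) / 2, x$k))
  invisible(x)
}

#' Symmetric normalization of a self-looped adjacency matrix
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `D` is the diagonal degree
#' matrix of `A + I`. This is the propagation operator of a graph
#' convolutional layer; the added self-loop guarantees positive degrees, and
#' the result is symmetric with eigenvalues in `[-1, 1]`.
#'
#' @param A Square binary adjacency matrix (dense or sparse), zero diagonal.
#' @return Sparse symmetric matrix of the same dimension.
#' @export
normalize_adjacency <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  A_t <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(A_t)
  inv_sqrt <- Matrix::Diagonal(x = 1 / sqrt(d))
  methods::as(inv_sqrt %*% A_t %*% inv_sqrt, "generalMatrix")
}

#' Row-normalized neighbor-averaging operator
#'
#' Internal helper: sparse matrix `R` with `R[i, j] = 1/deg(i)` for each
#' neighbor `j` of `i` (no self-loop), so `R %*% Z` is the per-spot mean of
#' neighbor embeddings used by the subgraph readout.
#' @noRd
neighbor_mean_operator <- function(graph) {
  A <- graph$adjacency
  d <- Matrix::rowSums(A)
  if (any(d == 0)) stop("graph has isolated spots; readout undefined")
  Matrix::Diagonal(x = 1 / d) %*% A
}

#' Write a graph as an edge-list TSV
#'
#' Dumps each undirected edge once (`i < j`, 1-based indices) with a header,
#' for external inspection.
#'
#' @param graph A `spot_graph`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  tri <- Matrix::which(Matrix::triu(graph$adjacency, k = 1) != 0, arr.ind = TRUE)
  utils::write.table(data.frame(i = tri[, 1], j = tri[, 2]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
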