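# Signature-gene cell-cell graph. The expression matrix is restricted to
# the union of the tumor and normal signature genes, reduced by PCA, and a
# k-nearest-neighbor graph is turned into smooth connectivity weights by
# the fuzzy simplicial-set construction (local kernel bandwidths calibrated
# so each cell's membership mass is log2(k), then fuzzy-union
# symmetrization). Restricting the graph to signature genes makes its
# communities align with tumor/normal states rather than generic cell types.

# exact k nearest neighbors by blockwise Euclidean distances (base R);
# returns list(index, dist) of n x k matrices, self excluded
.knn_exact <- function(emb, k, block = 512L) {
  n <- nrow(emb)
  stopifnot(k < n)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * emb[rows, , drop = FALSE] %*% t(emb)
    d2[d2 < 0] <- 0
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- d2[j, ]; di[i] <- Inf
      ord <- order(di, method = "radix")[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(di[ord])
    }
  }
  list(index = idx, dist = dst)
}

# per-cell bandwidth: binary search sigma so that
# sum_j exp(-(d_ij - rho_i)/sigma) = log2(k)
.smooth_knn_sigma <- function(d, rho, target, n_iter = 64, tol = 1e-5) {
  lo <- 0; hi <- Inf; mid <- 1
  adj <- pmax(d - rho, 0)
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-adj / mid))
    if (abs(val - target) < tol) break
    if (val > target) { hi <- mid; mid <- (lo + hi) / 2 }
    else { lo <- mid; mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2 }
  }
  mid
}

#' Build the signature-gene cell-cell graph
#'
#' @param dataset An [expression_dataset()].
#' @param tumor_signature,normal_signature [gene_signature()] objects (or
#'   character vectors); the graph uses the union of their genes.
#' @param k Number of nearest neighbors (default 30; must be < cell count).
#' @param n_pcs Number of principal components (default 50, capped at the
#'   available dimensionality).
#' @return An object of class `cell_graph`: list with `connectivities`
#'   (sparse symmetric nonnegative dgCMatrix, zero diagonal, weights in
#'   \[0, 1\]), `k`, `n_components_used`, `cell_ids`.
#' @export
build_cell_graph <- function(dataset, tumor_signature, normal_signature,
                             k = 30, n_pcs = 50) {
  stopifnot(inherits(dataset, "expression_dataset"))
  g1 <- if (inherits(tumor_signature, "gene_signature"))
    tumor_signature$genes else as.character(tumor_signature)
  g2 <- if (inherits(normal_signature, "gene_signature"))
    normal_signature$genes else as.character(normal_signature)
  genes <- intersect(union(g1, g2), dataset$gene_symbols)
  if (length(genes) < 2)
    stop("fewer than 2 signature genes present in the dataset", call. = FALSE)
  n <- nrow(dataset$matrix)
  if (k >= n)
    stop(sprintf("configuration error: k = %d must be < number of cells (%d)",
                 k, n), call. = FALSE)
  x <- dataset$matrix[, genes, drop = FALSE]
  rank_max <- min(n_pcs, ncol(x), n - 1L)
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = rank_max)
  emb <- pr$x
  nn <- .knn_exact(emb, k)
  target <- log2(k)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  p <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- nn$dist[i, ]
    rho <- d[1]
    sigma <- .smooth_knn_sigma(d, rho, target)
    p[i, ] <- exp(-pmax(d - rho, 0) / sigma)
  }
  P <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nn$index)),
                            x = as.numeric(t(p)), dims = c(n, n))
  # fuzzy union: W = P + P' - P o P'
  W <- P + Matrix::t(P) - P * Matrix::t(P)
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  dimnames(W) <- list(dataset$cell_ids, dataset$cell_ids)
  structure(list(connectivities = W, k = as.integer(k),
                 n_components_used = rank_max,
                 cell_ids = dataset$cell_ids),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, k = %d, %d PCs, %d nonzero edges\n",
              nrow(x$connectivities), x$k, x$n_components_used,
              Matrix::nnzero(x$connectivities)))
  invisible(x)
}
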