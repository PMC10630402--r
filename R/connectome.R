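#' Edge index map for upper-triangle vectorization
#'
#' Connectivity matrices are vectorized by taking the upper triangle in
#' row-major order: for node pairs (i, j) with i < j, the flat edge index k
#' runs (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). Node ids are 1-based.
#' All modules in the package share this convention, so edge masks computed
#' on one dataset can be applied to any other dataset with the same node
#' count.
#'
#' @param n_nodes number of atlas nodes (>= 2).
#' @return data.frame with columns `k` (1-based edge index), `i`, `j`
#'   (1-based node ids, i < j) and `label` ("n{i}_n{j}").
#' @examples
#' edge_index_map(3)  # three edges: (1,2), (1,3), (2,3)
#' @export
edge_index_map <- function(n_nodes) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2)
    stop("n_nodes must be a single integer >= 2")
  n <- as.integer(n_nodes)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(k = seq_along(i), i = i, j = j,
             label = paste0("n", i, "_n", j),
             stringsAsFactors = FALSE)
}

#' Number of edges for a node count
#' @param n_nodes number of nodes
#' @return n_nodes * (n_nodes - 1) / 2
#' @export
n_edges <- function(n_nodes) as.integer(n_nodes * (n_nodes - 1) / 2)

#' @rdname edge_index_map
#' @export
edge_labels <- function(n_nodes) edge_index_map(n_nodes)$label

#' Average voxel signals into node timecourses
#'
#' Parcellation by framewise averaging: the node signal at frame t is the
#' mean over that node's voxels at frame t. Operates on already-extracted
#' numeric arrays; image I/O and preprocessing are out of scope.
#'
#' @param voxel_signals voxels x frames numeric matrix.
#' @param labels integer vector of length nrow(voxel_signals) assigning each
#'   voxel to a node id (1-based, contiguous).
#' @return nodes x frames matrix of node timecourses, rows ordered by node id.
#' @export
parcellate <- function(voxel_signals, labels) {
  voxel_signals <- as.matrix(voxel_signals)
  if (length(labels) != nrow(voxel_signals))
    stop("labels must have one entry per voxel (row of voxel_signals)")
  labels <- as.integer(labels)
  ids <- sort(unique(labels))
  missing_ids <- setdiff(seq_len(max(ids)), ids)
  if (length(missing_ids))
    stop("empty node(s) with no assigned voxels: ",
         paste(missing_ids, collapse = ", "))
  counts <- tabulate(labels)
  rowsum(voxel_signals, labels) / counts
}

#' Fisher-z Pearson connectivity matrix from node timecourses
#'
#' Computes the Pearson correlation between every pair of node timecourses
#' and applies the Fisher r-to-z transform atanh(r). The diagonal is set to
#' NA: z of r = 1 is infinite and the self-connection is never consumed
#' downstream.
#'
#' @param ts nodes x frames numeric matrix (each row one node's timecourse).
#' @return nodes x nodes symmetric matrix of Fisher-z correlations with NA
#'   diagonal.
#' @export
connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 frames")
  v <- apply(ts, 1L, stats::var)
  if (any(v <= 0 | !is.finite(v)))
    stop("zero-variance node(s): ", paste(which(v <= 0 | !is.finite(v)),
                                          collapse = ", "))
  r <- stats::cor(t(ts))
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1))
    stop("degenerate node pair with |r| = 1 (duplicate or mirrored signal)")
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Extracts the strictly-upper triangle in the package's row-major edge
#' order (see [edge_index_map()]). For the 268-node Shen atlas this yields
#' 35778 edge features.
#'
#' @param m symmetric nodes x nodes matrix (diagonal ignored).
#' @param tol asymmetry tolerance.
#' @return numeric edge vector of length n(n-1)/2, named by edge labels.
#' @export
vectorize_upper <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (ncol(m) != n) stop("matrix must be square")
  lo <- m[lower.tri(m)]
  up <- t(m)[lower.tri(m)]
  if (any(abs(lo - up) > tol, na.rm = TRUE))
    stop("matrix is asymmetric beyond tolerance ", format(tol))
  v <- up  # t(m)[lower.tri] walks the upper triangle of m in row-major order
  names(v) <- edge_labels(n)
  v
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()] off the diagonal; the diagonal is NA.
#'
#' @param v edge vector of length n(n-1)/2.
#' @param n_nodes node count; inferred from length(v) if missing.
#' @return symmetric n x n matrix with NA diagonal.
#' @export
devectorize_upper <- function(v, n_nodes = NULL) {
  if (is.null(n_nodes)) {
    n_nodes <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (n_nodes != round(n_nodes))
      stop("length(v) is not a triangular number; give n_nodes explicitly")
  }
  n <- as.integer(n_nodes)
  if (length(v) != n * (n - 1L) / 2L)
    stop("edge vector length does not match n_nodes")
  m <- matrix(NA_real_, n, n)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
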