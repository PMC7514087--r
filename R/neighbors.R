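#' Euclidean distance matrix
#'
#' Exact O(n^2) pairwise Euclidean distances; symmetric with a zero diagonal.
#'
#' @param P A [pointset()] or numeric matrix with no missing cells.
#' @return An `n x n` numeric matrix.
#' @export
pairwise_distances <- function(P) {
  X <- if (inherits(P, "pointset")) P$X else as.matrix(P)
  if (anyNA(X)) stop("missing cells present")
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}

#' K-nearest-neighbor sets
#'
#' For each point i builds sigma(i), its K nearest neighbors by Euclidean
#' distance, self excluded, distance-ascending with ties broken by ascending
#' point index so every downstream step is reproducible.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param K Neighbor count, `1 <= K <= n - 1`.
#' @return An object of class `neighbor_model`: list with `K`, `nbr_idx`
#'   (`n x K` integer, row i is sigma(i)), `nbr_dist` (`n x K` numeric).
#' @export
knn_sets <- function(D, K) {
  n <- nrow(D)
  K <- as.integer(K)
  if (K < 1L || K > n - 1L)
    stop("K must satisfy 1 <= K <= n - 1 (n = ", n, ", K = ", K, ")")
  nbr_idx <- matrix(0L, n, K)
  nbr_dist <- matrix(0, n, K)
  idx <- seq_len(n)
  for (i in idx) {
    others <- idx[-i]
    # order() is stable, so equal distances fall back to ascending index
    o <- others[order(D[i, others])][seq_len(K)]
    nbr_idx[i, ] <- o
    nbr_dist[i, ] <- D[i, o]
  }
  structure(list(K = K, n = n, nbr_idx = nbr_idx, nbr_dist = nbr_dist),
            class = "neighbor_model")
}

#' @export
print.neighbor_model <- function(x, ...) {
  cat(sprintf("neighbor_model: n = %d, K = %d\n", x$n, x$K))
  invisible(x)
}

#' Common-neighbor set omega(i, j)
#'
#' The intersection of the K-nearest-neighbor sets sigma(i) and sigma(j). May
#' contain i or j themselves when each lies in the other's neighbor list.
#'
#' @param nm A `neighbor_model` from [knn_sets()].
#' @param i,j Distinct point indices (1-based).
#' @return Integer vector of shared neighbor indices (ascending).
#' @export
common_neighbors <- function(nm, i, j) {
  if (i == j) stop("common_neighbors requires i != j")
  sort(intersect(nm$nbr_idx[i, ], nm$nbr_idx[j, ]))
}

#' Mutual K-nearest-neighbor predicate
#'
#' TRUE iff i and j are K-nearest neighbors of each other.
#'
#' @inheritParams common_neighbors
#' @return Logical scalar.
#' @export
is_mutual <- function(nm, i, j) {
  if (i == j) stop("is_mutual requires i != j")
  (j %in% nm$nbr_idx[i, ]) && (i %in% nm$nbr_idx[j, ])
}

# n x n 0/1 neighbor indicator: A[i, p] = 1 iff p is in sigma(i).
# crossprod-style products over it give |omega| counts for all pairs at once.
neighbor_indicator <- function(nm) {
  A <- matrix(0, nm$n, nm$n)
  A[cbind(rep(seq_len(nm$n), nm$K), as.vector(nm$nbr_idx))] <- 1
  A
}

# Dense helpers shared by the density and assignment stages:
#  - common_count[i, j] = |omega(i, j)|
#  - mutual[i, j] = TRUE iff i, j are mutual K-nearest neighbors
neighbor_structure <- function(nm) {
  A <- neighbor_indicator(nm)
  list(A = A,
       common_count = tcrossprod(A),
       mutual = (A == 1) & (t(A) == 1))
}
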