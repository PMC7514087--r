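#' Parameters for potential-field-diffusion clustering
#'
#' @param K Neighbor count for the KNN graph. Values outside 4..50 trigger a
#'   warning: below 4 the similar-point threshold leaves step-1 allocation
#'   with nothing to propagate, and above 50 extra neighbors change little.
#' @param k Diffusion layers for the potential-field spread (1..3 warned
#'   range; each extra layer multiplies cost by K).
#' @param eps_floor Small positive floor guarding zero denominators when
#'   duplicate points collapse a common-neighbor distance sum to 0.
#' @param diffusion If FALSE the diffusion factor is dropped (similarity is
#'   the bare potential field theta) — the ablated variant that ignores
#'   global structure and over-weights dense clusters.
#' @param symmetrize If TRUE the similarity matrix is averaged with its
#'   transpose. Default FALSE: the diffusion sum starts from sigma(i) only,
#'   so the similarity is asymmetric as defined.
#' @return A `pfd_params` list.
#' @export
pfd_params <- function(K = 10L, k = 1L, eps_floor = 1e-12,
                       diffusion = TRUE, symmetrize = FALSE) {
  K <- as.integer(K); k <- as.integer(k)
  if (K < 1L) stop("K must be >= 1")
  if (k < 1L) stop("k (diffusion layers) must be >= 1")
  if (eps_floor <= 0) stop("eps_floor must be > 0")
  if (K < 4L || K > 50L)
    warning("K = ", K, " is outside the validated range [4, 50]")
  if (k > 3L)
    warning("k = ", k, " is outside the validated range [1, 3]")
  structure(list(K = K, k = k, eps_floor = eps_floor,
                 diffusion = isTRUE(diffusion),
                 symmetrize = isTRUE(symmetrize)),
            class = "pfd_params")
}

#' Potential field theta(i, j)
#'
#' Cumulative potential of the common neighbors of a mutual K-nearest-neighbor
#' pair: |omega(i,j)|^2 divided by the summed squared distances from i and j
#' to each common neighbor. Zero for non-mutual pairs and empty omega.
#'
#' @param nm A `neighbor_model` from [knn_sets()].
#' @param D Distance matrix.
#' @param i,j Distinct point indices.
#' @param eps_floor Denominator floor (see [pfd_params()]).
#' @return Non-negative scalar.
#' @export
potential_field <- function(nm, D, i, j, eps_floor = 1e-12) {
  if (i == j) stop("potential_field requires i != j")
  if (!is_mutual(nm, i, j)) return(0)
  om <- common_neighbors(nm, i, j)
  if (length(om) == 0L) return(0)
  denom <- sum(D[i, om]^2 + D[j, om]^2)
  length(om)^2 / max(denom, eps_floor)
}

#' k-layer diffusion sums S_k for every point
#'
#' S_k(i) totals, over all K^k directed paths i -> x1 -> ... -> xk walking the
#' KNN graph (x1 in sigma(i), x_{t+1} in sigma(x_t), revisits allowed), the
#' sum of squared edge distances along the path. Computed by the recursion
#' S_1(i) = sum_m d_im^2; S_t(i) = sum_{m in sigma(i)} (d_im^2 K^{t-1} +
#' S_{t-1}(m)), which is exact because each first edge is shared by K^{t-1}
#' continuations.
#'
#' @param nm A `neighbor_model`.
#' @param k Number of diffusion layers (`>= 1`).
#' @return Numeric vector of length n.
#' @export
diffusion_sums <- function(nm, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  nd2 <- nm$nbr_dist^2
  S1 <- rowSums(nd2)
  S <- S1
  if (k > 1L) {
    for (t in 2:k) {
      prev_at_nbrs <- matrix(S[nm$nbr_idx], nm$n, nm$K)
      S <- nm$K^(t - 1) * S1 + rowSums(prev_at_nbrs)
    }
  }
  S
}

#' Single-point diffusion sum S_k(i)
#' @inheritParams diffusion_sums
#' @param i Point index.
#' @return Scalar S_k(i).
#' @export
diffusion_sum <- function(nm, i, k) diffusion_sums(nm, k)[i]

#' Potential-field-diffusion similarity Theta(i, j)
#'
#' theta(i, j) amplified by the k-layer diffusion mass S_k(i): the similarity
#' factors exactly as |omega|^2 S_k(i) / sum_p (d_ip^2 + d_jp^2) for mutual
#' pairs, else 0. Asymmetric in (i, j) because diffusion starts at i.
#'
#' @inheritParams potential_field
#' @param params A [pfd_params()].
#' @return Non-negative scalar.
#' @export
pfd_similarity <- function(nm, D, i, j, params) {
  th <- potential_field(nm, D, i, j, params$eps_floor)
  if (th == 0 || !params$diffusion) return(th)
  th * diffusion_sum(nm, i, params$k)
}

#' Full similarity field over mutual K-nearest-neighbor pairs
#'
#' Builds the theta matrix, the diffusion sums S_k, and the similarity matrix
#' Theta in one pass. Theta is nonzero only on mutual pairs, so each row has
#' at most K nonzero entries.
#'
#' @param nm A `neighbor_model`.
#' @param D Distance matrix.
#' @param params A [pfd_params()].
#' @return A `similarity_field`: list with `theta` (n x n), `S` (length n),
#'   `Theta` (n x n), and the `mutual` logical matrix.
#' @export
similarity_field <- function(nm, D, params) {
  n <- nm$n
  ns <- neighbor_structure(nm)
  theta <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    for (j in nm$nbr_idx[i, ]) {
      if (j <= i || !ns$mutual[i, j]) next
      om <- intersect(nm$nbr_idx[i, ], nm$nbr_idx[j, ])
      if (length(om) == 0L) next
      denom <- sum(D2[i, om] + D2[j, om])
      theta[i, j] <- theta[j, i] <-
        length(om)^2 / max(denom, params$eps_floor)
    }
  }
  S <- diffusion_sums(nm, params$k)
  Theta <- if (params$diffusion) theta * S else theta  # row-scaled by S_k(i)
  if (params$symmetrize) Theta <- (Theta + t(Theta)) / 2
  structure(list(theta = theta, S = S, Theta = Theta, mutual = ns$mutual),
            class = "similarity_field")
}

#' Local density rho from the similarity field
#'
#' rho_i sums the K largest similarities Theta(i, .) (ties by ascending
#' index). Since a row has at most K nonzero entries this equals the sum of
#' all nonzero Theta(i, .).
#'
#' @param sf A `similarity_field`.
#' @param K Neighbor count.
#' @return Numeric vector of length n.
#' @export
local_density <- function(sf, K) {
  n <- nrow(sf$Theta)
  vapply(seq_len(n), function(i) {
    v <- sf$Theta[i, -i]
    sum(sort(v, decreasing = TRUE)[seq_len(min(K, n - 1L))])
  }, numeric(1))
}

#' Distance to the nearest strictly denser point
#'
#' For each point, delta is the minimum distance to any point of strictly
#' higher density and parent is that arg-min (ties by ascending index).
#' Density maxima get delta = max over the other points' delta values and
#' parent = -1; if every point is a maximum (all densities equal), delta is
#' the maximum pairwise distance.
#'
#' @param rho Density vector.
#' @param D Distance matrix.
#' @return List with numeric `delta` and integer `parent` (-1 for maxima).
#' @export
nearest_denser <- function(rho, D) {
  n <- length(rho)
  if (n == 1L) return(list(delta = 0, parent = -1L))
  delta <- numeric(n)
  parent <- integer(n)
  has_denser <- logical(n)
  for (i in seq_len(n)) {
    denser <- which(rho > rho[i])
    if (length(denser) == 0L) { parent[i] <- -1L; next }
    has_denser[i] <- TRUE
    d <- D[i, denser]
    p <- denser[which.min(d)]  # which.min takes the first, i.e. lowest index
    delta[i] <- D[i, p]
    parent[i] <- p
  }
  maxima <- !has_denser
  delta[maxima] <- if (any(has_denser)) max(delta[has_denser]) else max(D)
  list(delta = delta, parent = parent)
}

#' Decision values gamma = rho * delta
#' @param rho,delta Equal-length numeric vectors.
#' @return Numeric vector.
#' @export
decision_values <- function(rho, delta) {
  stopifnot(length(rho) == length(delta))
  rho * delta
}

#' Per-point peak statistics (rho, delta, parent, gamma)
#'
#' Convenience wrapper running [local_density()], [nearest_denser()] and
#' [decision_values()].
#'
#' @param sf A `similarity_field`.
#' @param D Distance matrix.
#' @param K Neighbor count.
#' @return A `peak_stats` list with `rho`, `delta`, `parent`, `gamma`.
#' @export
peak_stats <- function(sf, D, K) {
  rho <- local_density(sf, K)
  nd <- nearest_denser(rho, D)
  structure(list(rho = rho, delta = nd$delta, parent = nd$parent,
                 gamma = decision_values(rho, nd$delta)),
            class = "peak_stats")
}

#' Export the decision graph as a TSV table
#'
#' Writes (index, rho, delta, gamma), sorted gamma-descending with ties by
#' ascending index, for external plotting of the rho-delta or gamma decision
#' graph used to choose the number of clusters.
#'
#' @param stats A `peak_stats`.
#' @param path Output path.
#' @export
export_decision_graph <- function(stats, path) {
  ord <- order(-stats$gamma, seq_along(stats$gamma))
  df <- data.frame(index = ord, rho = stats$rho[ord],
                   delta = stats$delta[ord], gamma = stats$gamma[ord])
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a decision graph written by [export_decision_graph()]
#' @param path Path to the TSV.
#' @return data.frame with columns index, rho, delta, gamma.
#' @export
read_decision_graph <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("integer", rep("numeric", 3)))
}
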