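#' Select cluster centers by decision value
#'
#' The m points with the largest gamma become centers; ties break by
#' ascending index. Center labels 1..m follow descending gamma.
#'
#' @param gamma Decision-value vector.
#' @param m Number of clusters, `1 <= m <= n`.
#' @return Integer vector of m center indices, label order.
#' @export
select_centers <- function(gamma, m) {
  n <- length(gamma)
  m <- as.integer(m)
  if (m < 1L || m > n) stop("m must satisfy 1 <= m <= n")
  order(-gamma, seq_len(n))[seq_len(m)]
}

#' Similar-point predicate
#'
#' Two points are similar when they share strictly more than ceiling((K+1)/2)
#' common K-nearest neighbors — more than half the neighborhood regardless of
#' the parity of K.
#'
#' @param nm A `neighbor_model`.
#' @param i,j Distinct point indices.
#' @param K Neighbor count (defaults to the model's K).
#' @return Logical scalar.
#' @export
is_similar <- function(nm, i, j, K = nm$K) {
  if (i == j) stop("is_similar requires i != j")
  length(common_neighbors(nm, i, j)) > ceiling((K + 1) / 2)
}

#' Step 1: breadth-first allocation along similar-point chains
#'
#' A FIFO queue is seeded with the centers in label (descending-gamma) order.
#' Each dequeued element claims every still-unallocated point similar to it
#' (scanned in ascending index), labels it and appends it to the queue;
#' contested points therefore go to the first-dequeued claimant. Terminates
#' when no element yields new similar points.
#'
#' @param nm A `neighbor_model`.
#' @param centers Center indices in label order (from [select_centers()]).
#' @param K Neighbor count.
#' @return List with `labels` (NA for unallocated) and `phase` (character,
#'   "center" / "similar_bfs" / NA).
#' @export
allocate_similar <- function(nm, centers, K = nm$K) {
  n <- nm$n
  labels <- rep(NA_integer_, n)
  phase <- rep(NA_character_, n)
  labels[centers] <- seq_along(centers)
  phase[centers] <- "center"
  cc <- neighbor_structure(nm)$common_count
  thr <- ceiling((K + 1) / 2)
  queue <- centers
  head <- 1L
  while (head <= length(queue)) {
    e <- queue[head]; head <- head + 1L
    cand <- which(is.na(labels) & cc[e, ] > thr)
    cand <- cand[cand != e]
    if (length(cand)) {
      labels[cand] <- labels[e]
      phase[cand] <- "similar_bfs"
      queue <- c(queue, cand)
    }
  }
  list(labels = labels, phase = phase)
}

#' Step 2: KNN majority-vote allocation of the remaining points
#'
#' Unallocated points are processed in descending density (ties by index).
#' Each counts the labels among its K' nearest neighbors, starting at
#' K' = K and using every label assigned so far (including earlier step-2
#' labels); a unique plurality cluster wins, otherwise K' grows by 1 and the
#' vote repeats. K' is capped at n - 1, after which the point takes the label
#' of its nearest labeled point.
#'
#' @param nm A `neighbor_model`.
#' @param D Distance matrix.
#' @param labels Partial labels (NA = unallocated) from [allocate_similar()].
#' @param rho Density vector ordering the traversal.
#' @param K Starting neighborhood size.
#' @return Complete integer label vector.
#' @export
allocate_knn_vote <- function(nm, D, labels, rho, K = nm$K) {
  n <- length(labels)
  if (all(is.na(labels))) stop("no labeled point to vote from")
  todo <- which(is.na(labels))
  todo <- todo[order(-rho[todo], todo)]
  for (i in todo) {
    others <- seq_len(n)[-i]
    ord <- others[order(D[i, others])]  # stable: ties by ascending index
    Kp <- K
    repeat {
      if (Kp > n - 1L) {
        lab_near <- ord[!is.na(labels[ord])][1L]
        labels[i] <- labels[lab_near]
        break
      }
      votes <- labels[ord[seq_len(Kp)]]
      votes <- votes[!is.na(votes)]
      if (length(votes)) {
        tab <- table(votes)
        top <- tab[tab == max(tab)]
        if (length(top) == 1L) {
          labels[i] <- as.integer(names(top))
          break
        }
      }
      Kp <- Kp + 1L
    }
  }
  labels
}

#' Potential-field-diffusion density peak clustering
#'
#' The full pipeline: optional preprocessing (mean imputation + min-max
#' normalization), distance matrix, KNN graph, potential-field similarity
#' with k-layer diffusion, density peaks (rho, delta, gamma), top-gamma
#' center selection, then two-step allocation (similar-point breadth-first
#' propagation followed by KNN majority voting). Fully deterministic.
#'
#' @param P A [pointset()], numeric matrix, or data frame.
#' @param m Number of clusters (the algorithm does not pick it; read the
#'   decision graph or pass the known count).
#' @param params A [pfd_params()]; or pass `K`/`k` directly.
#' @param K,k Convenience shortcuts overriding `params`.
#' @param normalize If TRUE (default) impute feature means and min-max
#'   normalize before clustering.
#' @return A `pfd_clustering` object: list with `labels` (1..m), `centers`
#'   (label order), `phase` (per point: "center", "similar_bfs", "knn_vote"),
#'   `stats` (a `peak_stats`), `field` (the `similarity_field`), `params`,
#'   `m`, and `D`.
#' @examples
#' P <- make_fixture("gauss_grid", seed = 1)
#' cl <- pfd_dpc(P, m = 15, K = 14, k = 1)
#' table(cl$labels, P$y_true)
#' @export
pfd_dpc <- function(P, m, params = NULL, K = NULL, k = NULL,
                    normalize = TRUE) {
  if (!inherits(P, "pointset")) P <- pointset(P)
  if (is.null(params)) params <- pfd_params(K = if (is.null(K)) 10L else K,
                                            k = if (is.null(k)) 1L else k)
  if (!is.null(K)) params$K <- as.integer(K)
  if (!is.null(k)) params$k <- as.integer(k)
  n <- nrow(P$X)
  m <- as.integer(m)
  if (m < 1L || m > n) stop("m must satisfy 1 <= m <= n")
  if (params$K > n - 1L) stop("K must be <= n - 1")
  if (normalize) {
    P <- impute_mean(P)$points
    P <- minmax_normalize(P)$points
  } else if (anyNA(P$X)) stop("missing cells present and normalize = FALSE")
  D <- pairwise_distances(P)
  nm <- knn_sets(D, params$K)
  sf <- similarity_field(nm, D, params)
  st <- peak_stats(sf, D, params$K)
  centers <- select_centers(st$gamma, m)
  step1 <- allocate_similar(nm, centers, params$K)
  labels <- allocate_knn_vote(nm, D, step1$labels, st$rho, params$K)
  phase <- step1$phase
  phase[is.na(phase)] <- "knn_vote"
  structure(list(labels = labels, centers = centers, phase = phase,
                 stats = st, field = sf, params = params, m = m, D = D),
            class = "pfd_clustering")
}

#' @export
print.pfd_clustering <- function(x, ...) {
  cat(sprintf("pfd_dpc clustering: %d points, %d clusters (K = %d, k = %d%s)\n",
              length(x$labels), x$m, x$params$K, x$params$k,
              if (x$params$diffusion) "" else ", diffusion off"))
  cat("cluster sizes:", paste(tabulate(x$labels, x$m), collapse = " "), "\n")
  cat("allocation phases:",
      paste(names(table(x$phase)), table(x$phase), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
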