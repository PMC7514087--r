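#' Contingency table and pair counts for two labelings
#'
#' Cross-tabulates the two partitions and derives the four pair statistics:
#' `a` pairs co-clustered in both, `b` pairs separated in both, `c` pairs
#' co-clustered in the reference only, `d` pairs co-clustered in the
#' prediction only; a + b + c + d = N(N-1)/2.
#'
#' @param y_true,y_pred Equal-length label vectors (any integer coding).
#' @return A `contingency_table` list: `counts` matrix, `N`, row/column
#'   marginals `a_i`, `b_j`, and pair counts `a`, `b`, `c`, `d`.
#' @export
contingency <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  N <- length(y_true)
  if (N < 2L) stop("need at least 2 points")
  counts <- unname(table(y_true, y_pred))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts))
  a_i <- rowSums(counts)
  b_j <- colSums(counts)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(counts))
  same_r <- sum(ch2(a_i))
  same_c <- sum(ch2(b_j))
  cc <- same_r - a
  dd <- same_c - a
  bb <- ch2(N) - a - cc - dd
  structure(list(counts = counts, N = N, a_i = a_i, b_j = b_j,
                 a = a, b = bb, c = cc, d = dd),
            class = "contingency_table")
}

as_contingency <- function(ct, y_pred = NULL) {
  if (inherits(ct, "contingency_table")) ct else contingency(ct, y_pred)
}

#' Fowlkes-Mallows index
#'
#' Geometric mean of pairwise precision and recall:
#' a / sqrt((a + c)(a + d)). When both partitions are all singletons
#' (a + c = 0) the index is 1 for identical partitions and 0 otherwise.
#'
#' @param ct A `contingency_table`, or `y_true` when `y_pred` is given.
#' @param y_pred Optional predicted labels (with raw `y_true` in `ct`).
#' @return Scalar in [0, 1].
#' @export
fmi <- function(ct, y_pred = NULL) {
  ct <- as_contingency(ct, y_pred)
  if (ct$a + ct$c == 0 || ct$a + ct$d == 0) {
    return(if (ct$c == 0 && ct$d == 0) 1 else 0)
  }
  ct$a / sqrt((ct$a + ct$c) * (ct$a + ct$d))
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation model:
#' (RI - E[RI]) / (max RI - E[RI]) over the contingency table. 1 for
#' identical partitions (and for the degenerate case where both partitions
#' are trivial), near 0 in expectation for independent labelings.
#'
#' @inheritParams fmi
#' @return Scalar <= 1.
#' @export
ari <- function(ct, y_pred = NULL) {
  ct <- as_contingency(ct, y_pred)
  ch2 <- function(x) x * (x - 1) / 2
  sum_comb <- ct$a
  sum_r <- sum(ch2(ct$a_i))
  sum_c <- sum(ch2(ct$b_j))
  total <- ch2(ct$N)
  expected <- sum_r * sum_c / total
  max_index <- (sum_r + sum_c) / 2
  if (max_index == expected) return(1)
  (sum_comb - expected) / (max_index - expected)
}

# expected mutual information under the permutation (hypergeometric) model,
# natural log; O(sum over cells of marginal range) — fine at benchmark sizes
expected_mi <- function(a_i, b_j, N) {
  lgN <- lgamma(N + 1)
  emi <- 0
  for (ai in a_i) {
    for (bj in b_j) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_term <- log(nij / N) + log(N) + log(nij) - log(ai) - log(bj)
      # log hypergeometric pmf of nij given marginals ai, bj
      log_p <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(N - ai + 1) + lgamma(N - bj + 1) - lgN -
        lgamma(nij + 1) - lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      emi <- emi + sum(nij / N * (log(N * nij) - log(ai * bj)) * exp(log_p))
    }
  }
  emi
}

shannon_entropy <- function(marginal, N) {
  p <- marginal[marginal > 0] / N
  -sum(p * log(p))
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance: (MI - E[MI]) / (mean(H(R), H(C))
#' - E[MI]), with the expected MI taken under the permutation model and
#' arithmetic-mean normalization; natural logarithms throughout (the base
#' cancels in the ratio). 1 for identical partitions; can be negative when
#' agreement is below chance. Both partitions being a single cluster gives 1.
#'
#' @inheritParams fmi
#' @return Scalar <= 1.
#' @export
ami <- function(ct, y_pred = NULL) {
  ct <- as_contingency(ct, y_pred)
  R <- nrow(ct$counts); C <- ncol(ct$counts)
  if (R == 1L && C == 1L) return(1)
  N <- ct$N
  P <- ct$counts / N
  pr <- ct$a_i / N
  pc <- ct$b_j / N
  nz <- P > 0
  mi <- sum(P[nz] * (log(P[nz]) - log(outer(pr, pc))[nz]))
  emi <- expected_mi(ct$a_i, ct$b_j, N)
  h_mean <- (shannon_entropy(ct$a_i, N) + shannon_entropy(ct$b_j, N)) / 2
  denom <- h_mean - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  (mi - emi) / denom
}

#' All three external validation indices at once
#'
#' @param y_true Reference (ground-truth) labels.
#' @param y_pred Predicted cluster labels.
#' @return Named numeric vector with `ami`, `ari`, `fmi`.
#' @examples
#' cluster_metrics(c(1, 1, 2, 2), c(1, 1, 2, 2))  # all 1
#' @export
cluster_metrics <- function(y_true, y_pred) {
  ct <- contingency(y_true, y_pred)
  c(ami = ami(ct), ari = ari(ct), fmi = fmi(ct))
}
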