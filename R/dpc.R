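#' Cutoff indicator chi(x)
#'
#' 1 when x < 0, 0 otherwise: counting kernel of the classic density peak
#' cutoff density.
#'
#' @param x Numeric vector.
#' @return 0/1 numeric vector.
#' @export
chi <- function(x) as.numeric(x < 0)

#' Baseline density peak parameters
#'
#' @param dc_value Cutoff distance: an absolute distance
#'   (`dc_mode = "absolute"`) or a percent position in the sorted pairwise
#'   distance list (`dc_mode = "percent"`, default — the usual 1-2 percent
#'   neighborhood-fraction heuristic).
#' @param dc_mode `"percent"` or `"absolute"`.
#' @param kernel `"cutoff"` (integer counts) or `"gaussian"` (continuous).
#' @return A `dpc_params` list.
#' @export
dpc_params <- function(dc_value = 2, dc_mode = c("percent", "absolute"),
                       kernel = c("cutoff", "gaussian")) {
  dc_mode <- match.arg(dc_mode)
  kernel <- match.arg(kernel)
  if (dc_value <= 0) stop("dc_value must be > 0")
  if (dc_mode == "percent" && dc_value >= 100)
    stop("percent dc_value must lie in (0, 100)")
  structure(list(dc_value = dc_value, dc_mode = dc_mode, kernel = kernel),
            class = "dpc_params")
}

#' Resolve a percent cutoff to an absolute distance
#'
#' dc is the value at 1-based position round(p/100 * M), clamped to [1, M],
#' in the ascending list of the M = n(n-1)/2 pairwise distances.
#'
#' @param D Distance matrix.
#' @param p Percent in (0, 100).
#' @return Absolute cutoff distance.
#' @export
dc_from_percent <- function(D, p) {
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 points")
  if (p <= 0 || p >= 100) stop("p must lie in (0, 100)")
  dists <- sort(D[upper.tri(D)])
  M <- length(dists)
  pos <- min(max(round(p / 100 * M), 1L), M)
  dists[pos]
}

#' Classic density peak local density
#'
#' Cutoff kernel: rho_i counts the points strictly within dc of i. Gaussian
#' kernel: rho_i = sum_{j != i} exp(-(d_ij / dc)^2).
#'
#' @param D Distance matrix.
#' @param dc Absolute cutoff distance.
#' @param kernel `"cutoff"` or `"gaussian"`.
#' @return Density vector.
#' @export
dpc_density <- function(D, dc, kernel = c("cutoff", "gaussian")) {
  kernel <- match.arg(kernel)
  n <- nrow(D)
  offdiag <- function(i) D[i, -i]
  vapply(seq_len(n), function(i) {
    d <- offdiag(i)
    if (kernel == "cutoff") sum(chi(d - dc)) else sum(exp(-(d / dc)^2))
  }, numeric(1))
}

#' Nearest-denser distances for the baseline (same contract as
#' [nearest_denser()])
#' @inheritParams nearest_denser
#' @return List with `delta` and `parent`.
#' @export
dpc_delta <- function(rho, D) nearest_denser(rho, D)

#' Baseline decision values gamma = rho * delta
#' @inheritParams decision_values
#' @return Numeric vector.
#' @export
dpc_gamma <- function(rho, delta) decision_values(rho, delta)

#' Descending-density label inheritance
#'
#' Points are traversed in descending density; every non-center inherits the
#' label of its nearest strictly denser point (its parent), which has always
#' been labeled before it — the single-step allocation whose one wrong
#' assignment cascades into the attached allocation error.
#'
#' @param rho Density vector.
#' @param parent Parent index per point (-1 for density maxima).
#' @param centers Center indices in label order.
#' @param D Distance matrix (used only when a non-center density maximum has
#'   no parent: it takes its nearest center's label).
#' @return Integer label vector.
#' @export
dpc_assign <- function(rho, parent, centers, D = NULL) {
  n <- length(rho)
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  ord <- order(-rho, seq_len(n))
  for (i in ord) {
    if (!is.na(labels[i])) next
    if (parent[i] > 0L) {
      labels[i] <- labels[parent[i]]
    } else {
      if (is.null(D)) stop("non-center density maximum needs D to fall back")
      labels[i] <- labels[centers[which.min(D[i, centers])]]
    }
  }
  labels
}

#' Halo (noise) flags via the border-density rule
#'
#' Per cluster, the border set holds its points lying strictly within dc of
#' any point of another cluster; the cluster threshold is the maximum density
#' over that border set (0 when empty) and members with rho below the
#' threshold are flagged halo.
#'
#' @param labels Complete label vector.
#' @param rho Density vector.
#' @param D Distance matrix.
#' @param dc Absolute cutoff distance.
#' @return Logical halo flag per point.
#' @export
dpc_halo <- function(labels, rho, D, dc) {
  n <- length(labels)
  halo <- logical(n)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    others <- which(labels != cl)
    if (length(others) == 0L) next
    border <- members[vapply(members, function(i)
      any(D[i, others] < dc), logical(1))]
    thr <- if (length(border)) max(rho[border]) else 0
    halo[members] <- rho[members] < thr
  }
  halo
}

#' Classic density peak clustering (baseline)
#'
#' The three-step baseline: density (cutoff or Gaussian kernel), nearest
#' denser distances, top-gamma centers, descending-density label
#' inheritance, and optionally the border/halo noise rule.
#'
#' @param P A [pointset()], matrix or data frame.
#' @param m Number of clusters.
#' @param params A [dpc_params()].
#' @param normalize If TRUE (default) impute + min-max normalize first.
#' @param halo If TRUE also compute halo flags.
#' @return A `dpc_clustering` list: `labels`, `centers`, `halo`, `rho`,
#'   `delta`, `parent`, `gamma`, `dc`, `params`.
#' @export
dpc <- function(P, m, params = dpc_params(), normalize = TRUE, halo = TRUE) {
  if (!inherits(P, "pointset")) P <- pointset(P)
  m <- as.integer(m)
  n <- nrow(P$X)
  if (m < 1L || m > n) stop("m must satisfy 1 <= m <= n")
  if (normalize) {
    P <- impute_mean(P)$points
    P <- minmax_normalize(P)$points
  }
  D <- pairwise_distances(P)
  dc <- if (params$dc_mode == "percent")
    dc_from_percent(D, params$dc_value) else params$dc_value
  rho <- dpc_density(D, dc, params$kernel)
  nd <- dpc_delta(rho, D)
  gamma <- dpc_gamma(rho, nd$delta)
  centers <- select_centers(gamma, m)
  labels <- dpc_assign(rho, nd$parent, centers, D)
  halo_flags <- if (halo) dpc_halo(labels, rho, D, dc) else logical(n)
  structure(list(labels = labels, centers = centers, halo = halo_flags,
                 rho = rho, delta = nd$delta, parent = nd$parent,
                 gamma = gamma, dc = dc, params = params, D = D),
            class = "dpc_clustering")
}

#' @export
print.dpc_clustering <- function(x, ...) {
  cat(sprintf(
    "dpc clustering: %d points, %d clusters (%s kernel, dc = %.4g, %d halo)\n",
    length(x$labels), length(x$centers), x$params$kernel, x$dc, sum(x$halo)))
  invisible(x)
}
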