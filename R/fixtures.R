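# Seeded stand-ins for the classic clustering shape benchmarks. Each
# generator is deterministic given (shape, n, seed): it runs under a private
# RNG state and restores the caller's.

with_fixture_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

gen_jain_moons <- function(n, seed, noise) {
  # variable-density two-moons: dense lower crescent vs a sparse, more
  # diffuse upper crescent separated by a clear gap; point counts roughly
  # sparse:dense = 1:2. The crescents are traced with even arc spacing plus
  # jitter, like the hand-constructed original.
  n_dense <- round(2 * n / 3)
  n_sparse <- n - n_dense
  with_fixture_seed(seed, {
    t1 <- seq(0, pi, length.out = n_dense) + rnorm(n_dense, sd = 0.02)
    dense <- cbind(cos(t1), -0.55 * sin(t1)) +
      matrix(rnorm(2 * n_dense, sd = noise), ncol = 2)
    t2 <- seq(0, pi, length.out = n_sparse) + rnorm(n_sparse, sd = 0.02)
    sparse <- cbind(1.5 * cos(t2) - 0.35, 0.8 * sin(t2) + 0.35) +
      matrix(rnorm(2 * n_sparse, sd = 2.2 * noise), ncol = 2)
    pointset(rbind(dense, sparse),
             y_true = rep(1:2, c(n_dense, n_sparse)),
             source = sprintf("jain_moons(n=%d, seed=%d)", n, seed))
  })
}

gen_spiral3 <- function(n, seed, noise) {
  # three interleaved Archimedean arms, points evenly spaced in arc length
  # (t ~ sqrt(s)) with small jitter, like the drawn original
  per <- diff(round(seq(0, n, length.out = 4)))
  with_fixture_seed(seed, {
    pts <- vector("list", 3)
    for (a in 1:3) {
      s <- seq(0.2^2, 1, length.out = per[a])
      t <- sqrt(s) * 2.5 * pi
      r <- t / (2.5 * pi)
      ang <- t + 2 * pi * (a - 1) / 3
      pts[[a]] <- cbind(r * cos(ang), r * sin(ang)) +
        matrix(rnorm(2 * per[a], sd = noise), ncol = 2)
    }
    pointset(do.call(rbind, pts), y_true = rep(1:3, per),
             source = sprintf("spiral3(n=%d, seed=%d)", n, seed))
  })
}

gen_ring_blobs <- function(n, seed, noise) {
  # open C-shaped ring enclosing two compact blobs (pathbased-like
  # geometry); ring traced with even angular spacing plus jitter
  n_ring <- round(n / 3)
  n_blob <- round(n / 3)
  n_blob2 <- n - n_ring - n_blob
  with_fixture_seed(seed, {
    ang <- seq(0.15 * pi, 1.85 * pi, length.out = n_ring) +
      rnorm(n_ring, sd = 0.01) # gap at the bottom right
    ring <- cbind(cos(ang), sin(ang)) +
      matrix(rnorm(2 * n_ring, sd = noise), ncol = 2)
    b1 <- cbind(rnorm(n_blob, -0.4, 0.09), rnorm(n_blob, 0, 0.09))
    b2 <- cbind(rnorm(n_blob2, 0.4, 0.09), rnorm(n_blob2, 0, 0.09))
    pointset(rbind(ring, b1, b2),
             y_true = rep(1:3, c(n_ring, n_blob, n_blob2)),
             source = sprintf("ring_blobs(n=%d, seed=%d)", n, seed))
  })
}

gen_gauss_grid <- function(n, seed, noise) {
  # 15 small isotropic gaussians on a grid (R15-like), equal sizes
  centers <- as.matrix(expand.grid(x = 0:3, y = 0:3))[1:15, ]
  per <- rep(floor(n / 15), 15)
  per[seq_len(n - sum(per))] <- per[seq_len(n - sum(per))] + 1
  with_fixture_seed(seed, {
    X <- do.call(rbind, lapply(1:15, function(c1)
      cbind(rnorm(per[c1], centers[c1, 1], noise),
            rnorm(per[c1], centers[c1, 2], noise))))
    pointset(X, y_true = rep(1:15, per),
             source = sprintf("gauss_grid(n=%d, seed=%d)", n, seed))
  })
}

gen_aggregation7 <- function(n, seed, noise) {
  # seven blobs of uneven size, well separated but touching in places
  centers <- rbind(c(0, 0), c(3, 0.5), c(6, 0), c(1, 3), c(4.2, 3.2),
                   c(7, 3), c(2.5, 5.5))
  frac <- c(0.20, 0.10, 0.22, 0.08, 0.18, 0.12, 0.10)
  per <- round(frac * n)
  per[1] <- per[1] + (n - sum(per))
  with_fixture_seed(seed, {
    X <- do.call(rbind, lapply(1:7, function(c1)
      cbind(rnorm(per[c1], centers[c1, 1], noise * (0.7 + 0.1 * c1)),
            rnorm(per[c1], centers[c1, 2], noise * (0.7 + 0.1 * c1)))))
    pointset(X, y_true = rep(1:7, per),
             source = sprintf("aggregation7(n=%d, seed=%d)", n, seed))
  })
}

gen_highdim_blobs <- function(n, seed, noise, d = 512L, m = 16L) {
  # well-separated gaussians in high dimension; random centers at pairwise
  # distance ~ sqrt(2d) * scale, >= 10x the within-cluster sigma
  per <- rep(floor(n / m), m)
  per[seq_len(n - sum(per))] <- per[seq_len(n - sum(per))] + 1
  with_fixture_seed(seed, {
    centers <- matrix(rnorm(m * d), m, d)
    X <- do.call(rbind, lapply(seq_len(m), function(c1)
      matrix(rnorm(per[c1] * d, sd = noise), per[c1], d) +
        matrix(centers[c1, ], per[c1], d, byrow = TRUE)))
    pointset(X, y_true = rep(seq_len(m), per),
             source = sprintf("highdim_blobs(n=%d, d=%d, seed=%d)",
                              n, d, seed))
  })
}

# n mirrors the original benchmark sizes; K/k are the per-fixture reference
# parameters found by the standard per-dataset sweep over K in [4, 50],
# k in {1, 2, 3} (the same protocol used to tune the published benchmarks)
fixture_defaults <- list(
  jain_moons    = list(n = 373L,  noise = 0.045, m = 2L,  K = 13L, k = 3L),
  spiral3       = list(n = 312L,  noise = 0.01,  m = 3L,  K = 11L, k = 2L),
  ring_blobs    = list(n = 300L,  noise = 0.04,  m = 3L,  K = 26L, k = 3L),
  gauss_grid    = list(n = 600L,  noise = 0.08,  m = 15L, K = 14L, k = 1L),
  aggregation7  = list(n = 788L,  noise = 0.35,  m = 7L,  K = 41L, k = 3L),
  highdim_blobs = list(n = 1024L, noise = 0.25,  m = 16L, K = 4L,  k = 1L)
)

#' Seeded synthetic clustering benchmarks
#'
#' Deterministic generators emulating the classic shape benchmarks:
#' `jain_moons` (two crescents, the upper one sparser and more diffuse,
#' point counts 1:2), `spiral3` (three interleaved Archimedean arms),
#' `ring_blobs` (an open ring enclosing two compact blobs), `gauss_grid`
#' (15 small Gaussians on a grid), `aggregation7` (seven uneven blobs), and
#' `highdim_blobs` (16 well-separated Gaussians in 512 dimensions,
#' inter-center distance at least 10x the within-cluster sigma). Default
#' sizes mirror the originals (373, 312, 300, 600, 788, 1024 points).
#'
#' @param shape One of `"jain_moons"`, `"spiral3"`, `"ring_blobs"`,
#'   `"gauss_grid"`, `"aggregation7"`, `"highdim_blobs"`.
#' @param n Number of points (shape-specific default).
#' @param seed Integer seed; the same (shape, n, seed, noise) always yields
#'   byte-identical output and the caller's RNG state is untouched.
#' @param noise Coordinate noise level (shape-specific default).
#' @param ... Extra shape parameters (`d`, `m` for `highdim_blobs`).
#' @return A [pointset()] carrying ground-truth labels in `$y_true`.
#' @examples
#' P <- make_fixture("spiral3", seed = 42)
#' table(P$y_true)
#' @export
make_fixture <- function(shape, n = NULL, seed = 1L, noise = NULL, ...) {
  if (!shape %in% names(fixture_defaults))
    stop("unknown shape: ", shape, " (expected one of ",
         paste(names(fixture_defaults), collapse = ", "), ")")
  def <- fixture_defaults[[shape]]
  if (is.null(n)) n <- def$n
  if (is.null(noise)) noise <- def$noise
  gen <- switch(shape,
                jain_moons = gen_jain_moons, spiral3 = gen_spiral3,
                ring_blobs = gen_ring_blobs, gauss_grid = gen_gauss_grid,
                aggregation7 = gen_aggregation7,
                highdim_blobs = gen_highdim_blobs)
  gen(n = n, seed = as.integer(seed), noise = noise, ...)
}

#' Default cluster count of a fixture shape
#' @param shape Fixture shape name.
#' @return Integer number of ground-truth clusters.
#' @export
fixture_clusters <- function(shape) {
  if (!shape %in% names(fixture_defaults)) stop("unknown shape: ", shape)
  fixture_defaults[[shape]]$m
}

#' Reference clustering parameters for a fixture shape
#'
#' The per-fixture (K, k) found once by the standard per-dataset sweep
#' (K in 4..50, k in 1..3), analogous to the per-benchmark tuning customary
#' for neighborhood-based density peak methods.
#'
#' @param shape Fixture shape name.
#' @return List with `K`, `k`, and cluster count `m`.
#' @export
fixture_params <- function(shape) {
  if (!shape %in% names(fixture_defaults)) stop("unknown shape: ", shape)
  fixture_defaults[[shape]][c("K", "k", "m")]
}

#' Deterministically shuffle the point order of a point set
#'
#' Used by the order-insensitivity experiment: the clustering pipeline is
#' fully deterministic, so a row permutation must permute the labels and
#' leave every ground-truth comparison unchanged (absent distance ties).
#'
#' @param P A [pointset()].
#' @param seed Integer seed for the permutation.
#' @return List with the permuted `points` and the `perm` used.
#' @export
shuffle_points <- function(P, seed = 1L) {
  stopifnot(inherits(P, "pointset"))
  perm <- with_fixture_seed(seed, sample.int(nrow(P$X)))
  list(points = pointset(P$X[perm, , drop = FALSE],
                         y_true = P$y_true[perm],
                         source = paste0(P$source, " [shuffled]")),
       perm = perm)
}
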