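# The collinear 0/1/3/7 micro-instance with K = 2 is worked through by hand
# in several blocks below (indices here are 1-based: points 1..4).
micro <- local({
  D <- pairwise_distances(matrix(c(0, 1, 3, 7), ncol = 1))
  list(D = D, nm = knn_sets(D, 2))
})

test_that("potential_field matches hand-computed values and zero branches", {
  with(micro, {
    expect_equal(potential_field(nm, D, 1, 2), 1 / 13)
    expect_equal(potential_field(nm, D, 1, 3), 0.2)
    # non-mutual pair -> 0
    expect_false(is_mutual(nm, 1, 4))
    expect_equal(potential_field(nm, D, 1, 4), 0)
    expect_error(potential_field(nm, D, 2, 2), "i != j")
  })
})

test_that("diffusion sums follow the path recursion on worked examples", {
  with(micro, {
    expect_equal(diffusion_sum(nm, 1, 1), 10)     # 1^2 + 3^2
    expect_equal(diffusion_sum(nm, 1, 2), 38)     # 2 + 5 + 13 + 18
  })
  # 3-point line 0,1,3 with K = 1: only path 1 -> 2 -> 1 gives 1 + 1
  D3 <- pairwise_distances(matrix(c(0, 1, 3), ncol = 1))
  nm3 <- knn_sets(D3, 1)
  expect_equal(diffusion_sum(nm3, 1, 2), 2)
  expect_error(diffusion_sums(micro$nm, 0), "k must be >= 1")
})

test_that("diffusion recursion equals exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    K <- sample(1:3, 1)
    k <- sample(1:3, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    D <- pairwise_distances(X)
    nm <- knn_sets(D, min(K, n - 1L))
    S <- diffusion_sums(nm, k)
    for (i in seq_len(n))
      expect_equal(S[i], brute_diffusion_sum(nm, D, i, k), tolerance = 1e-9)
  }
})

test_that("pfd_similarity factors as theta * S_k on mutual pairs", {
  p <- suppressWarnings(pfd_params(K = 2, k = 1))
  with(micro, {
    expect_equal(pfd_similarity(nm, D, 1, 3, p), 2.0)
    expect_equal(pfd_similarity(nm, D, 1, 2, p), 10 / 13)
    expect_equal(pfd_similarity(nm, D, 1, 4, p), 0)
    sf <- similarity_field(nm, D, p)
    # matrix route agrees with the scalar route everywhere
    for (i in 1:4) for (j in setdiff(1:4, i))
      expect_equal(sf$Theta[i, j], pfd_similarity(nm, D, i, j, p))
    # theta symmetric, Theta supported on mutual pairs only
    expect_equal(sf$theta, t(sf$theta))
    expect_true(all(sf$Theta[!sf$mutual] == 0))
  })
})

test_that("local_density sums the top-K similarities", {
  p <- suppressWarnings(pfd_params(K = 2, k = 1))
  with(micro, {
    sf <- similarity_field(nm, D, p)
    rho <- local_density(sf, 2)
    expect_equal(rho[1], 36 / 13)
    expect_equal(rho, brute_local_density(sf$Theta, 2))
  })
  # larger random instance against the brute-force top-K oracle
  set.seed(55)
  X <- matrix(rnorm(80), 40, 2)
  D <- pairwise_distances(X)
  nm <- knn_sets(D, 6)
  sf <- similarity_field(nm, D, pfd_params(K = 6, k = 2))
  expect_equal(local_density(sf, 6), brute_local_density(sf$Theta, 6))
  # a point with no mutual neighbors has rho 0: isolated far outlier
  Xo <- rbind(matrix(rnorm(30, sd = 0.2), 15, 2), c(500, 500))
  Do <- pairwise_distances(Xo)
  nmo <- knn_sets(Do, 4)
  sfo <- similarity_field(nmo, Do, pfd_params(K = 4, k = 1))
  expect_equal(local_density(sfo, 4)[16], 0)
})

test_that("nearest_denser implements the min-distance-to-denser rule", {
  # two-point case
  nd <- nearest_denser(c(2, 1), matrix(c(0, 4, 4, 0), 2, 2))
  expect_equal(nd$delta, c(4, 4))
  expect_identical(nd$parent, c(-1L, 1L))

  # line 0,1,3 with rho = (3,1,2)
  D <- pairwise_distances(matrix(c(0, 1, 3), ncol = 1))
  nd2 <- nearest_denser(c(3, 1, 2), D)
  expect_equal(nd2$delta, c(3, 1, 3))
  expect_identical(nd2$parent, c(-1L, 1L, 1L))

  # all-equal densities: every point a maximum, delta = max pairwise dist
  nd3 <- nearest_denser(c(1, 1, 1), D)
  expect_identical(nd3$parent, c(-1L, -1L, -1L))
  expect_equal(nd3$delta, rep(3, 3))

  # parent is strictly denser and delta is the distance to it
  set.seed(77)
  rho <- runif(30)
  Dr <- pairwise_distances(matrix(rnorm(60), 30, 2))
  nd4 <- nearest_denser(rho, Dr)
  for (i in which(nd4$parent > 0)) {
    expect_gt(rho[nd4$parent[i]], rho[i])
    expect_equal(nd4$delta[i], Dr[i, nd4$parent[i]])
  }
})

test_that("decision values multiply rho and delta", {
  expect_equal(decision_values(c(3, 1, 2), c(3, 1, 3)), c(9, 1, 6))
  expect_equal(decision_values(c(0, 2), c(5, 1)), c(0, 2))
  expect_error(decision_values(1:3, 1:2))
})

test_that("decision graph round-trips through the TSV export", {
  st <- structure(list(rho = c(3, 1, 2), delta = c(3, 1, 3),
                       parent = c(-1L, 1L, 1L), gamma = c(9, 1, 6)),
                  class = "peak_stats")
  f <- withr::local_tempfile()
  export_decision_graph(st, f)
  dg <- read_decision_graph(f)
  expect_identical(dg$index, c(1L, 3L, 2L))   # gamma descending
  expect_equal(dg$gamma, c(9, 6, 1))
  expect_equal(dg$rho, st$rho[dg$index])
  expect_equal(dg$delta, st$delta[dg$index], tolerance = 1e-15)
})

test_that("similarity and density are invariant to rigid motion and scale", {
  set.seed(42)
  X <- matrix(rnorm(60), 30, 2)
  p <- pfd_params(K = 5, k = 2)
  base <- local({
    D <- pairwise_distances(X)
    nm <- knn_sets(D, 5)
    sf <- similarity_field(nm, D, p)
    list(sf = sf, st = peak_stats(sf, D, 5))
  })
  for (tf in list(function(X) sweep(X, 2, c(3, -7), "+"),
                  function(X) X %*% rotation2(1.1),
                  function(X) X * 4)) {
    Xt <- tf(X)
    Dt <- pairwise_distances(Xt)
    nmt <- knn_sets(Dt, 5)
    sft <- similarity_field(nmt, Dt, p)
    stt <- peak_stats(sft, Dt, 5)
    expect_equal(sft$Theta, base$sf$Theta, tolerance = 1e-8)
    expect_equal(stt$rho, base$st$rho, tolerance = 1e-8)
  }
  # scaling by c multiplies delta and gamma by c
  Ds <- pairwise_distances(X * 4)
  sts <- peak_stats(similarity_field(knn_sets(Ds, 5), Ds, p), Ds, 5)
  expect_equal(sts$delta, 4 * base$st$delta, tolerance = 1e-8)
  expect_equal(sts$gamma, 4 * base$st$gamma, tolerance = 1e-8)
})
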