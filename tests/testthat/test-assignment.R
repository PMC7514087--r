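test_that("select_centers takes the top-gamma points with index tie-breaks", {
  expect_identical(select_centers(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_centers(c(3, 1, 2), 3), c(1L, 3L, 2L))
  expect_identical(select_centers(c(1, 1, 1), 2), c(1L, 2L))
  expect_error(select_centers(c(1, 2), 3), "m must satisfy")
})

test_that("is_similar applies the strict more-than-half threshold", {
  # synthetic neighbor model with controlled overlap: 10 points on a line
  D <- pairwise_distances(matrix(seq(0, 9), ncol = 1))
  nm <- knn_sets(D, 4)   # threshold ceil(5/2) = 3
  # interior neighbors share |omega| computed from the actual sets
  for (pair in list(c(5, 6), c(4, 7), c(2, 9))) {
    i <- pair[1]; j <- pair[2]
    expect_identical(is_similar(nm, i, j),
                     length(common_neighbors(nm, i, j)) > 3)
    expect_identical(is_similar(nm, i, j), is_similar(nm, j, i))
  }
  # threshold arithmetic: K = 4 -> 3, K = 5 -> 3
  expect_equal(ceiling((4 + 1) / 2), 3)
  expect_equal(ceiling((5 + 1) / 2), 3)
  expect_error(is_similar(nm, 2, 2), "i != j")
})

test_that("allocate_similar chains labels breadth-first from the centers", {
  # two tight blobs: points similar within a blob, never across
  P <- tiny_blobs(n_per = 20, gap = 50, seed = 5)
  D <- pairwise_distances(P$X)
  nm <- knn_sets(D, 6)
  centers <- c(1L, 21L)
  out <- allocate_similar(nm, centers)
  expect_identical(out$labels[1], 1L)
  expect_identical(out$labels[21], 2L)
  expect_identical(out$phase[centers], c("center", "center"))
  got <- !is.na(out$labels)
  # no cross-blob contamination
  expect_true(all(out$labels[got][P$y_true[got] == 1] == 1))
  expect_true(all(out$labels[got][P$y_true[got] == 2] == 2))
  # labels reachable through a chain of is_similar edges from a center
  for (i in which(got & out$phase != "center")) {
    claimants <- which(got & out$labels == out$labels[i] &
                         seq_along(out$labels) != i)
    expect_true(any(vapply(claimants, function(j)
      is_similar(nm, i, j), logical(1))))
  }
})

test_that("allocate_knn_vote resolves majorities, grows ties, needs labels", {
  # hand-built situation: labeled core, one unlabeled point between
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 0), c(10, 1), c(5, 0.5))
  D <- pairwise_distances(X)
  nm <- knn_sets(D, 3)
  partial <- c(1L, 1L, 1L, 2L, 2L, NA)
  rho <- c(5, 4, 4, 5, 4, 1)
  labs <- allocate_knn_vote(nm, D, partial, rho, K = 3)
  expect_identical(labs[6], 1L)  # 3 nearest of point 6: {1,2} x A vs ...
  expect_false(anyNA(labs))
  expect_error(allocate_knn_vote(nm, D, rep(NA_integer_, 6), rho, 3),
               "no labeled point")

  # majority among labeled neighbors: {A, A, B} -> A
  X2 <- rbind(c(0, 0), c(0.5, 0), c(3, 0), c(1, 0.2))
  D2 <- pairwise_distances(X2)
  nm2 <- knn_sets(D2, 3)
  labs2 <- allocate_knn_vote(nm2, D2, c(1L, 1L, 2L, NA), c(3, 2, 3, 1), 3)
  expect_identical(labs2[4], 1L)

  # two-way tie at K' = 2 grows the window until it breaks
  X3 <- matrix(c(0, 1, 2.2, 3.1), ncol = 1)
  D3 <- pairwise_distances(X3)
  nm3 <- knn_sets(D3, 2)
  labs3 <- allocate_knn_vote(nm3, D3, c(1L, NA, 2L, 2L), c(3, 1, 3, 2), 2)
  expect_identical(labs3[2], 2L)  # K'=2 ties {1,2}; K'=3 sees {1,2,2}
})

test_that("pfd_dpc labels everything deterministically on blob data", {
  P <- tiny_blobs(n_per = 30, gap = 10, seed = 7)
  cl <- pfd_dpc(P, m = 2, K = 5, k = 1)
  expect_equal(unname(cluster_metrics(P$y_true, cl$labels)[["ami"]]), 1)
  expect_setequal(unique(cl$labels), 1:2)
  expect_identical(cl$labels[cl$centers], 1:2)
  expect_true(all(cl$phase %in% c("center", "similar_bfs", "knn_vote")))
  # determinism
  cl2 <- pfd_dpc(P, m = 2, K = 5, k = 1)
  expect_identical(cl$labels, cl2$labels)

  # m = n: every point its own center
  Ps <- pointset(matrix(rnorm(10), 5, 2))
  cln <- suppressWarnings(pfd_dpc(Ps, m = 5, K = 2, k = 1))
  expect_identical(sort(cln$labels), 1:5)
  expect_true(all(cln$phase == "center"))

  # duplicated point runs without error (eps_floor guard)
  Pd <- pointset(rbind(P$X, P$X[1, ]), y_true = c(P$y_true, 1L))
  cld <- pfd_dpc(Pd, m = 2, K = 5, k = 1)
  expect_false(anyNA(cld$labels))

  # parameter validation
  expect_error(suppressWarnings(pfd_dpc(Ps, m = 6, K = 2)),
               "m must satisfy")
  expect_error(suppressWarnings(pfd_dpc(Ps, m = 2, K = 5)), "K must be")
})

test_that("pipeline is permutation-equivariant on tie-free data", {
  P <- tiny_blobs(n_per = 25, gap = 8, seed = 13)
  cl <- pfd_dpc(P, m = 2, K = 6, k = 2)
  sh <- shuffle_points(P, seed = 99)
  cl_sh <- pfd_dpc(sh$points, m = 2, K = 6, k = 2)
  # same partition after undoing the permutation
  expect_equal(unname(
    cluster_metrics(cl$labels[sh$perm], cl_sh$labels)[["ari"]]), 1)
})
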