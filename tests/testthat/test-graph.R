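make_stack <- function(st, r = 10) compute_msngc(st, base_radius_xy = r)

test_that("k-NN of collinear spots with identical features picks the middle spot", {
  st <- spot_table(rbind(c(0, 0), c(1, 0), c(2, 0)), gene = rep("a", 3))
  m <- make_stack(st)
  kn <- knn_graph(st, m, k = 2)
  # endpoints' nearest is the middle spot (identical all-zero-variance MSNGC
  # gives rho 0 at every scale, so ST distance is proportional to Manhattan)
  expect_equal(kn$idx[1, 1], 2L)
  expect_equal(kn$idx[3, 1], 2L)
})

test_that("exact k-NN equals the brute-force all-pairs sort", {
  st <- random_field(100, n_genes = 5, extent = 50, seed = 31)
  m <- make_stack(st, 6)
  kn <- knn_graph(st, m, k = 5)
  d <- st_distance_matrix(st, m)
  for (i in seq_len(100)) {
    di <- d[i, ]; di[i] <- Inf
    o <- order(di, seq_len(100))[1:5]
    expect_identical(kn$idx[i, ], o)
  }
  expect_true(all(diff(t(kn$dist)) >= 0))  # ascending rows
})

test_that("duplicate spots appear in each other's lists at distance 0", {
  st <- spot_table(rbind(c(1, 1), c(1, 1), c(5, 5)), gene = c("a", "a", "b"))
  m <- make_stack(st)
  kn <- knn_graph(st, m, k = 2)
  expect_equal(kn$idx[1, 1], 2L)
  expect_equal(kn$idx[2, 1], 1L)
  expect_equal(kn$dist[1, 1], 0)
  expect_equal(kn$dist[2, 1], 0)
  expect_error(knn_graph(st, m, k = 3), "smaller")
})

test_that("NN-descent recovers the exact neighbor lists to high recall", {
  # The ST distance deliberately violates the triangle inequality (a high
  # MSNGC correlation shrinks a large physical separation), so a purely
  # local-join descent can miss the occasional far-in-space/close-in-feature
  # neighbor; recall is checked instead of strict equality, and distances of
  # recovered edges must be exact.
  st <- random_field(250, n_genes = 4, extent = 40, seed = 17)
  m <- make_stack(st, 6)
  exact <- knn_graph(st, m, k = 6)
  d <- st_distance_matrix(st, m)
  for (sd in c(1L, 99L)) {
    approx <- spotseg:::knn_nn_descent(st, m, k = 6, seed = sd)
    recall <- mean(vapply(seq_len(250), function(i) {
      length(intersect(approx$idx[i, ], exact$idx[i, ])) / 6
    }, numeric(1)))
    expect_gte(recall, 0.99)
    expect_equal(approx$dist,
                 matrix(d[cbind(rep(seq_len(250), 6), as.vector(approx$idx))],
                        ncol = 6), tolerance = 1e-9)
    expect_true(all(diff(t(approx$dist)) >= 0))
  }
})

test_that("bandwidth calibration hits the log2(k) weight-sum target", {
  # worked case: distances 1..4, target log2(4) = 2; compare to a scalar
  # uniroot oracle on 1 + e^{-1/s} + e^{-2/s} + e^{-3/s} = 2
  cal <- calibrate_bandwidth(c(1, 2, 3, 4), tol = 1e-7)
  expect_equal(cal$delta, 1)
  f <- function(s) 1 + exp(-1 / s) + exp(-2 / s) + exp(-3 / s) - 2
  s_oracle <- uniroot(f, c(1e-6, 100), tol = 1e-12)$root
  expect_equal(cal$sigma, s_oracle, tolerance = 1e-4)
  expect_lt(abs(cal$residual), 1e-7)
  expect_false(cal$flag)
})

test_that("calibration flags all-tied rows and errors on unsorted input", {
  cal <- calibrate_bandwidth(c(2, 2, 2, 2))
  expect_true(cal$flag)
  expect_equal(cal$sigma, 1e-3 * 2)   # pinned at the lower search bound
  expect_error(calibrate_bandwidth(c(3, 1, 2)), "ascending")
})

test_that("solvable random rows satisfy the calibration constraint", {
  set.seed(44)
  for (rep in 1:50) {
    k <- sample(2:60, 1)
    row <- sort(runif(k, 0, 10))
    cal <- calibrate_bandwidth(row, tol = 1e-6)
    if (!cal$flag) {
      wsum <- sum(exp(-pmax(row - cal$delta, 0) / cal$sigma))
      expect_lt(abs(wsum - log2(k)), 1e-6)
    }
  }
})

test_that("directed weights follow the clamped exponential kernel", {
  expect_equal(directed_weights(matrix(5), delta = 5, sigma = 2), matrix(1))
  expect_equal(directed_weights(matrix(7), delta = 5, sigma = 2),
               matrix(exp(-1)))
  # guard: D below delta clamps to weight 1
  expect_equal(directed_weights(matrix(3), delta = 5, sigma = 2), matrix(1))
  # nearest neighbor of every calibrated row gets exactly 1
  row <- sort(runif(10, 1, 4))
  cal <- calibrate_bandwidth(row)
  w <- directed_weights(matrix(row, 1), cal$delta, cal$sigma)
  expect_equal(w[1, 1], 1)
  expect_true(all(w > 0 & w <= 1))
})

test_that("fuzzy union matches its closed form and the dense oracle", {
  # one-sided edge keeps its weight; symmetric 0.5s combine to 0.75
  w <- rbind(c(1.0, 0.5), c(0.5, 0.2))
  idx <- rbind(c(2L, 3L), c(1L, 3L))
  a <- as.matrix(fuzzy_union(w, idx, n = 3))
  expect_equal(a[1, 2], 1 + 0.5 - 0.5)     # w12=1, w21=0.5
  expect_equal(a[2, 1], a[1, 2])
  expect_equal(a[1, 3], 0.5)               # one-sided
  expect_equal(a[2, 3], 0.2)
  set.seed(55)
  for (rep in 1:10) {
    n <- 30L; k <- 4L
    idx <- t(vapply(seq_len(n), function(i) sample(seq_len(n)[-i], k),
                    integer(k)))
    wts <- matrix(runif(n * k), n, k)
    a <- as.matrix(fuzzy_union(wts, idx, n = n))
    expect_equal(a, oracle_fuzzy_union(wts, idx, n), tolerance = 1e-12)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(a, t(a))
    expect_equal(diag(a), rep(0, n))
  }
})

test_that("fuzzy union is monotone in each directed weight", {
  idx <- rbind(c(2L,3L), c(1L,3L), c(1L,2L))
  w <- matrix(0.4, 3, 2)
  a0 <- as.matrix(fuzzy_union(w, idx, n = 3))
  w2 <- w; w2[1, 1] <- 0.9
  a1 <- as.matrix(fuzzy_union(w2, idx, n = 3))
  expect_true(all(a1 - a0 >= -1e-15))
})

test_that("spectral initialization separates two disconnected cliques", {
  n <- 10L
  a <- matrix(0, n, n)
  a[1:5, 1:5] <- 1; a[6:10, 6:10] <- 1
  diag(a) <- 0
  v <- spectral_init(Matrix::Matrix(a, sparse = TRUE), d = 1, seed = 2)
  expect_equal(dim(v), c(10L, 1L))
  expect_equal(max(abs(v)), 10)
  # all of one component strictly below the other after sign fixing
  expect_true(max(v[1:5, 1]) < min(v[6:10, 1]) ||
                max(v[6:10, 1]) < min(v[1:5, 1]))
  # oracle: eigenvectors of the dense normalized Laplacian
  deg <- rowSums(a)
  lap <- diag(n) - diag(1 / sqrt(deg)) %*% a %*% diag(1 / sqrt(deg))
  ev <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  expect_lt(abs(ev$values[n]), 1e-10)     # trivial eigenvalue 0 exists
  # the returned direction spans the second eigenvector (also eigenvalue 0
  # here): check it is an eigenvector of the Laplacian with eigenvalue ~0
  resid <- lap %*% v[, 1] - 0 * v[, 1]
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("spectral init is deterministic and matches dense/iterative paths", {
  set.seed(77)
  n <- 60L
  pts <- matrix(rnorm(n * 2), ncol = 2)
  a <- exp(-as.matrix(dist(pts)))
  diag(a) <- 0
  a_sp <- Matrix::Matrix(a, sparse = TRUE)
  v1 <- spectral_init(a_sp, d = 2, seed = 5)
  v2 <- spectral_init(a_sp, d = 2, seed = 5)
  expect_identical(v1, v2)
  # iterative subspace path agrees with the dense path up to sign/scale
  v_iter <- spectral_init(a_sp, d = 2, seed = 5, dense_cutoff = 1L,
                          n_iter = 500L)
  cors <- abs(diag(cor(v1, v_iter)))
  expect_true(all(cors > 0.999))
})

test_that("isolated vertices receive coordinates and d validates", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 0   # vertices 3, 4 isolated
  v <- spectral_init(Matrix::Matrix(a, sparse = TRUE), d = 1, seed = 3)
  expect_true(all(is.finite(v)))
  expect_error(spectral_init(Matrix::Matrix(a, sparse = TRUE), d = 5,
                             seed = 1), "eigenpairs")
})
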