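test_that("DBSCAN assigns noise, cores and borders as constructed", {
  # isolated point with min_samples 4 is noise
  pts <- rbind(matrix(rnorm(40, sd = 0.1), ncol = 2), c(50, 50))
  lab <- dbscan_labels(pts, eps = 1, min_samples = 4)
  expect_equal(lab[21], -1L)
  expect_true(all(lab[1:20] == lab[1]))
  # two blobs separated by 100 eps: exactly 2 clusters, no noise
  blob <- function(cx) cbind(runif(20, cx, cx + 0.5), runif(20, 0, 0.5))
  set.seed(20)
  pts2 <- rbind(blob(0), blob(100))
  lab2 <- dbscan_labels(pts2, eps = 1, min_samples = 4)
  expect_equal(sort(unique(lab2)), c(0L, 1L))
  expect_equal(lab2[1:20], rep(0L, 20))
  expect_equal(lab2[21:40], rep(1L, 20))
})

test_that("DBSCAN equals the reference implementation on random instances", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(20:150, 1)
    pts <- matrix(runif(n * 2, 0, 10), ncol = 2)
    eps <- runif(1, 0.3, 2)
    ms <- sample(1:6, 1)
    mine <- dbscan_labels(pts, eps, ms)
    ref <- oracle_dbscan(pts, eps, ms)
    expect_true(same_partition(mine, ref))
  }
})

test_that("noise count is non-increasing in eps", {
  set.seed(22)
  pts <- matrix(runif(300, 0, 10), ncol = 2)
  noise <- sapply(c(0.2, 0.4, 0.8, 1.6), function(e)
    sum(dbscan_labels(pts, e, 4) == -1L))
  expect_true(all(diff(noise) <= 0))
})

test_that("row permutation permutes labels equivariantly", {
  set.seed(23)
  pts <- matrix(runif(200, 0, 5), ncol = 2)
  perm <- sample.int(100)
  lab <- dbscan_labels(pts, 0.7, 4)
  lab_p <- dbscan_labels(pts[perm, ], 0.7, 4)
  expect_true(same_partition(lab[perm], lab_p))
})

test_that("cluster centers are the medoid-to-centroid members", {
  # singleton cluster is its own center
  pts <- rbind(c(0, 0), c(10, 10), c(10, 11), c(11, 10))
  lab <- c(0L, 1L, 1L, 1L)
  ctr <- cluster_centers(pts, lab)
  expect_equal(unname(ctr[1]), 1L)
  # symmetric square: all members tie, lowest index wins
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  expect_equal(unname(cluster_centers(sq, rep(0L, 4))[1]), 1L)
  # random cluster matches the exhaustive scan
  set.seed(24)
  p2 <- matrix(rnorm(100), ncol = 2)
  ctr2 <- cluster_centers(p2, rep(0L, 50))
  cm <- colMeans(p2)
  expect_equal(unname(ctr2[1]),
               which.min(colSums((t(p2) - cm)^2)))
  expect_error(cluster_centers(p2, rep(-1L, 50)), "noise")
})

test_that("end-to-end: two well-separated cells are recovered exactly", {
  # easy-preset statistical conditions (10 genes, Dirichlet 0.3 profiles,
  # 150 reads/cell) scaled down to two cells four radii apart
  sim <- simulate_spots(simulation_config(
    n_cells = 2L, n_cell_types = 2L, n_genes = 10L,
    mean_reads_per_cell = 150, cell_radius = 15,
    min_center_separation = 120, field_size = 200,
    type_profile_concentration = 0.3,
    background_rate = 0, seed = 1))
  res <- suppressWarnings(segment(sim$spots, segmentation_config(seed = 1)))
  expect_equal(res$n_clusters, 2L)
  expect_equal(adjusted_rand_index(sim$truth$spot_cell, res$labels), 1)
  expect_equal(length(res$labels), n_spots(sim$spots))
})

test_that("segment is deterministic and handles empty input", {
  sim <- simulate_spots(simulation_config(
    n_cells = 4L, n_genes = 6L, mean_reads_per_cell = 80,
    min_center_separation = 60, field_size = 220, seed = 5))
  cfg <- segmentation_config(seed = 9)
  r1 <- segment(sim$spots, cfg)
  r2 <- segment(sim$spots, cfg)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$embedding$coords, r2$embedding$coords)
  empty <- segment(spot_table(matrix(numeric(0), 0, 2), character(0)))
  expect_equal(length(empty$labels), 0L)
  expect_equal(empty$n_clusters, 0L)
})

test_that("filtered spots come back as -1 in the original index space", {
  sim <- simulate_spots(simulation_config(
    n_cells = 3L, n_genes = 5L, mean_reads_per_cell = 100,
    min_center_separation = 70, field_size = 250, seed = 6))
  # add a blatant outlier far outside the field
  st <- spot_table(rbind(sim$spots$coords, c(5e3, 5e3)),
                   gene = c(sim$spots$gene_names[sim$spots$gene_ids], "g01"))
  res <- segment(st, segmentation_config(filter_threshold = 50, seed = 2))
  expect_equal(res$labels[n_spots(st)], -1L)
  expect_false(res$kept[n_spots(st)])
  expect_gt(res$n_clusters, 0L)
})

test_that("center refinement keeps the adjacency valid and never collapses quality", {
  seeds <- 1:5
  drops <- numeric(0)
  for (s in seeds) {
    sim <- simulate_spots(simulation_config(
      n_cells = 8L, n_cell_types = 3L, n_genes = 8L,
      mean_reads_per_cell = 80, cell_radius = 12,
      min_center_separation = 40, field_size = 220,
      background_rate = 0, seed = s))
    base <- segment(sim$spots, segmentation_config(seed = s,
                                                   refine_rounds = 0))
    ref <- segment(sim$spots, segmentation_config(seed = s,
                                                  refine_rounds = 1))
    ari0 <- adjusted_rand_index(sim$truth$spot_cell, base$labels)
    ari1 <- adjusted_rand_index(sim$truth$spot_cell, ref$labels)
    drops <- c(drops, ari0 - ari1)
  }
  expect_true(all(drops <= 0.05))
})

test_that("refine_with_centers augments A within [0,1] and skips tiny center sets", {
  sim <- simulate_spots(simulation_config(
    n_cells = 5L, n_genes = 6L, mean_reads_per_cell = 60,
    min_center_separation = 50, field_size = 220, seed = 8))
  st <- sim$spots
  m <- compute_msngc(st)
  kn <- knn_graph(st, m, k = 10)
  cal <- spotseg:::calibrate_bandwidths(kn$dist)
  w <- directed_weights(kn$dist, cal$delta, cal$sigma)
  a_mat <- fuzzy_union(w, kn$idx, n = n_spots(st))
  centers <- c(1L, 80L, 160L, 230L, 290L)
  cfg <- segmentation_config(seed = 1)
  cfg$embedding$epochs <- 10L
  out <- refine_with_centers(st, m, a_mat, centers, cfg)
  a2 <- out$a_mat
  expect_true(all(a2@x >= -1e-12 & a2@x <= 1 + 1e-12))
  expect_equal(as.matrix(a2), t(as.matrix(a2)), tolerance = 1e-12)
  # existing edges are never weakened by the union
  expect_true(all(as.matrix(a2) - as.matrix(a_mat) >= -1e-12))
  expect_warning(refine_with_centers(st, m, a_mat, c(1L, 2L), cfg),
                 "skipped")
})

test_that("the default eps heuristic scales with min_samples and errors on tiny input", {
  set.seed(25)
  pts <- matrix(rnorm(400), ncol = 2)
  e4 <- default_eps(pts, min_samples = 4)
  e8 <- default_eps(pts, min_samples = 8)
  expect_gt(e8, e4)
  expect_error(default_eps(pts[1:3, ], min_samples = 4), "too few")
})
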