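test_that("zero background means every spot belongs to a cell", {
  sim <- simulate_spots(simulation_config(n_cells = 5L, background_rate = 0,
                                          min_center_separation = 60,
                                          field_size = 300, seed = 3))
  expect_true(all(sim$truth$spot_cell >= 1L))
  expect_equal(length(sim$truth$spot_cell), n_spots(sim$spots))
})

test_that("total read count concentrates around the Poisson mean", {
  sim <- simulate_spots(simulation_config(n_cells = 2L, n_genes = 5L,
                                          mean_reads_per_cell = 100,
                                          min_center_separation = 60,
                                          field_size = 200,
                                          background_rate = 0, seed = 4))
  n <- n_spots(sim$spots)
  expect_lt(abs(n - 200), 5 * sqrt(200))
})

test_that("empirical gene frequencies converge to the drawn profile", {
  cfg <- simulation_config(n_cells = 5L, n_cell_types = 1L, n_genes = 8L,
                           mean_reads_per_cell = 10000,
                           cell_radius = 10, min_center_separation = 25,
                           field_size = 200, background_rate = 0,
                           seed = 6)
  sim <- suppressWarnings(simulate_spots(cfg))
  expect_gt(n_spots(sim$spots), 45000)
  emp <- tabulate(sim$spots$gene_ids, 8) / n_spots(sim$spots)
  tv <- sum(abs(emp - sim$truth$type_profiles[1, ])) / 2
  expect_lt(tv, 0.01)
})

test_that("cell spots stay within the cell radius of their center", {
  sim <- simulate_spots(simulation_config(n_cells = 6L, cell_radius = 12,
                                          min_center_separation = 40,
                                          field_size = 300,
                                          background_rate = 0, seed = 7))
  for (ci in seq_len(6)) {
    ix <- sim$truth$spot_cell == ci
    offs <- sweep(sim$spots$coords[ix, , drop = FALSE], 2,
                  sim$truth$cell_centers[ci, ])
    expect_true(all(sqrt(rowSums(offs^2)) <= 12 + 1e-9))
  }
  expect_true(all(sim$spots$coords >= 0 & sim$spots$coords <= 300))
})

test_that("simulations are seed-deterministic and seeds differ", {
  cfg <- make_separable_preset("easy", seed = 11)
  s1 <- simulate_spots(cfg)
  s2 <- simulate_spots(cfg)
  expect_identical(s1$spots, s2$spots)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_spots(make_separable_preset("easy", seed = 12))
  expect_false(identical(s1$spots$coords, s3$spots$coords))
})

test_that("presets round-trip and unknown names are rejected", {
  for (p in c("easy", "medium", "hard")) {
    cfg <- make_separable_preset(p, seed = 1)
    expect_s3_class(cfg, "simulation_config")
    sim <- simulate_spots(cfg)
    expect_gt(n_spots(sim$spots), 100)
  }
  expect_error(make_separable_preset("impossible"), "easy, medium, hard")
})

test_that("hard preset: multi-scale features separate types better than single-scale", {
  sim <- simulate_spots(make_separable_preset("hard", seed = 2))
  st <- sim$spots
  m_multi <- compute_msngc(st, base_radius_xy = 10, scale_factors = c(1, 3, 5))
  m_single <- compute_msngc(st, base_radius_xy = 10, scale_factors = 1)
  # spot nearest each cell center carries the cell's context
  ctr_spot <- vapply(seq_len(sim$config$n_cells), function(ci) {
    ix <- which(sim$truth$spot_cell == ci)
    d2 <- colSums((t(st$coords[ix, , drop = FALSE]) -
                     sim$truth$cell_centers[ci, ])^2)
    ix[which.min(d2)]
  }, integer(1))
  types <- sim$truth$cell_type
  sep_stat <- function(stack) {
    same <- diff <- numeric(0)
    for (i in seq_along(ctr_spot)) {
      for (j in seq_along(ctr_spot)) {
        if (i >= j) next
        rho <- msngc_correlation(stack$counts[ctr_spot[i], , , drop = TRUE],
                                 stack$counts[ctr_spot[j], , , drop = TRUE])
        if (types[i] == types[j]) same <- c(same, rho) else diff <- c(diff, rho)
      }
    }
    mean(same) - mean(diff)
  }
  expect_gt(sep_stat(m_multi), sep_stat(m_single))
})

test_that("context annulus spots are background-labeled and sit at 2-4 radii", {
  cfg <- simulation_config(n_cells = 3L, mean_reads_per_cell = 100,
                           cell_radius = 10, min_center_separation = 100,
                           field_size = 400, background_rate = 0,
                           context_fraction = 0.5, seed = 9)
  sim <- simulate_spots(cfg)
  ctx <- which(sim$truth$spot_cell == -1L)
  expect_gt(length(ctx), 50)
  dmin <- vapply(ctx, function(i) {
    min(sqrt(colSums((t(sim$truth$cell_centers) -
                        sim$spots$coords[i, ])^2)))
  }, numeric(1))
  expect_true(all(dmin >= 2 * 10 - 1e-9 & dmin <= 4 * 10 + 1e-9))
})

test_that("simulation_config validates its fields", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_genes = 0L))
  expect_error(simulation_config(dims = 4L))
  expect_error(simulation_config(core_profile_mix = 2))
})
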