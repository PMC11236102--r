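#' Simulation configuration
#'
#' Parameters of the synthetic spot-cloud generator, which emulates the
#' structure of imaging-based spatial transcriptomics data: cells are compact
#' clusters of gene-tagged points, each cell type has its own gene-frequency
#' profile drawn once from a symmetric Dirichlet, and background noise spots
#' are scattered uniformly over the field.
#'
#' Two optional mechanisms support harder regimes where local composition
#' alone is uninformative:
#' * `core_profile_mix` mixes a shared baseline profile into every cell's
#'   own reads (at 1, all cell cores look transcriptomically identical);
#' * `context_fraction` places additional *context* spots in an annulus
#'   `[context_inner, context_outer] * cell_radius` around each cell center,
#'   carrying the cell's pure type profile but labeled as background (`-1`)
#'   in the ground truth — type identity is then readable only at mid/long
#'   neighborhood scales.
#'
#' @param n_cells number of cells.
#' @param n_cell_types number of cell types.
#' @param n_genes vocabulary size `L`.
#' @param mean_reads_per_cell Poisson mean of reads per cell.
#' @param cell_radius cell extent; spot offsets are an isotropic Gaussian
#'   (sd = `cell_radius / 2`) truncated at `cell_radius`.
#' @param min_center_separation minimum distance between cell centers
#'   (rejection sampling).
#' @param dims 2 or 3.
#' @param z_radius cell extent along z in 3D.
#' @param field_size side length of the square (cubic) field.
#' @param background_rate expected background spots per unit area (volume).
#' @param type_profile_concentration symmetric Dirichlet concentration of the
#'   per-type gene profiles (small = spiky, distinctive profiles).
#' @param core_profile_mix weight in `[0, 1]` of the shared baseline profile
#'   in cell reads (default 0 = pure type profiles).
#' @param context_fraction expected context spots per cell as a fraction of
#'   `mean_reads_per_cell` (default 0 = none).
#' @param context_inner,context_outer annulus bounds for context spots, in
#'   multiples of `cell_radius`.
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 30L, n_cell_types = 3L,
                              n_genes = 10L, mean_reads_per_cell = 150,
                              cell_radius = 15, min_center_separation = 60,
                              dims = 2L, z_radius = 10,
                              field_size = 420, background_rate = 0,
                              type_profile_concentration = 0.3,
                              core_profile_mix = 0,
                              context_fraction = 0,
                              context_inner = 2, context_outer = 4,
                              seed = 1L) {
  stopifnot(n_cells >= 1L, n_cell_types >= 1L, n_genes >= 1L,
            mean_reads_per_cell > 0, cell_radius > 0,
            dims %in% c(2L, 3L), z_radius > 0, field_size > 0,
            background_rate >= 0, type_profile_concentration > 0,
            core_profile_mix >= 0, core_profile_mix <= 1,
            context_fraction >= 0, context_inner > 0,
            context_outer > context_inner)
  # separations in [cell_radius, 2 cell_radius) give partly overlapping
  # cells — a supported, deliberately hard regime (see make_separable_preset)
  if (min_center_separation < cell_radius) {
    warning("min_center_separation below cell_radius: cells overlap heavily")
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_cell_types = as.integer(n_cell_types),
                 n_genes = as.integer(n_genes),
                 mean_reads_per_cell = mean_reads_per_cell,
                 cell_radius = cell_radius,
                 min_center_separation = min_center_separation,
                 dims = as.integer(dims), z_radius = z_radius,
                 field_size = field_size, background_rate = background_rate,
                 type_profile_concentration = type_profile_concentration,
                 core_profile_mix = core_profile_mix,
                 context_fraction = context_fraction,
                 context_inner = context_inner,
                 context_outer = context_outer,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# symmetric Dirichlet draws via normalized Gamma variates
rdirichlet_sym <- function(n, k, concentration) {
  g <- matrix(rgamma(n * k, shape = concentration, rate = 1), n, k)
  zero <- rowSums(g) == 0          # possible underflow for tiny concentration
  g[zero, ] <- 1
  g / rowSums(g)
}

#' Simulate a spot cloud with ground truth
#'
#' Generates a [spot_table] plus per-spot ground truth.  Per cell: a type is
#' drawn uniformly, the read count is Poisson, spot offsets are an isotropic
#' truncated Gaussian, and gene tags are multinomial draws from the type's
#' gene profile (optionally mixed with a shared baseline).  Background (and
#' context) spots carry ground-truth label `-1`.
#'
#' @param config a [simulation_config].
#' @return A list with
#'   * `spots`: the [spot_table] (cells first, then context, then background),
#'   * `truth`: list with `spot_cell` (per-spot cell index, `-1` background),
#'     `cell_type` (per-cell type id), `cell_centers` (matrix), and
#'     `type_profiles` (`n_cell_types x n_genes`).
#' @examples
#' sim <- simulate_spots(simulation_config(n_cells = 4, seed = 7))
#' table(sim$truth$spot_cell > 0)
#' @export
simulate_spots <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config
  L <- cfg$n_genes
  genes <- sprintf("g%02d", seq_len(L))

  type_profiles <- rdirichlet_sym(cfg$n_cell_types, L,
                                  cfg$type_profile_concentration)
  baseline <- as.vector(rdirichlet_sym(1L, L, 1))
  cell_type <- sample.int(cfg$n_cell_types, cfg$n_cells, replace = TRUE)

  # cell centers: uniform rejection sampling at min separation
  d <- cfg$dims
  centers <- matrix(NA_real_, cfg$n_cells, d)
  margin <- cfg$cell_radius
  placed <- 0L
  attempts <- 0L
  max_attempts <- 20000L * cfg$n_cells
  while (placed < cfg$n_cells) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", cfg$n_cells, " cells at separation ",
           cfg$min_center_separation, "; enlarge field_size")
    }
    cand <- runif(d, margin, cfg$field_size - margin)
    if (placed == 0L ||
        min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= cfg$min_center_separation) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }

  # truncated isotropic Gaussian offsets (z axis scaled for 3D)
  r_axis <- c(cfg$cell_radius, cfg$cell_radius,
              cfg$z_radius)[seq_len(d)]
  draw_offsets <- function(m) {
    out <- matrix(NA_real_, m, d)
    todo <- seq_len(m)
    while (length(todo)) {
      cand <- matrix(rnorm(length(todo) * d, sd = rep(r_axis / 2, each = length(todo))),
                     ncol = d)
      ok <- rowSums((cand / rep(r_axis, each = nrow(cand)))^2) <= 1
      out[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    out
  }

  coords_list <- list(); gene_list <- list(); cell_list <- list()
  for (ci in seq_len(cfg$n_cells)) {
    m <- rpois(1L, cfg$mean_reads_per_cell)
    if (m == 0L) next
    prof <- (1 - cfg$core_profile_mix) * type_profiles[cell_type[ci], ] +
      cfg$core_profile_mix * baseline
    coords_list[[length(coords_list) + 1L]] <-
      sweep(draw_offsets(m), 2L, centers[ci, ], "+")
    gene_list[[length(gene_list) + 1L]] <-
      sample.int(L, m, replace = TRUE, prob = prof)
    cell_list[[length(cell_list) + 1L]] <- rep(ci, m)
  }

  # context annulus spots: pure type profile, ground truth background
  if (cfg$context_fraction > 0) {
    for (ci in seq_len(cfg$n_cells)) {
      m <- rpois(1L, cfg$context_fraction * cfg$mean_reads_per_cell)
      if (m == 0L) next
      rad <- cfg$cell_radius *
        sqrt(runif(m, cfg$context_inner^2, cfg$context_outer^2))
      ang <- runif(m, 0, 2 * pi)
      off <- cbind(rad * cos(ang), rad * sin(ang))
      if (d == 3L) off <- cbind(off, runif(m, -cfg$z_radius, cfg$z_radius))
      coords_list[[length(coords_list) + 1L]] <-
        sweep(off, 2L, centers[ci, ], "+")
      gene_list[[length(gene_list) + 1L]] <-
        sample.int(L, m, replace = TRUE,
                   prob = type_profiles[cell_type[ci], ])
      cell_list[[length(cell_list) + 1L]] <- rep(-1L, m)
    }
  }

  # uniform background noise
  if (cfg$background_rate > 0) {
    vol <- cfg$field_size^d
    m <- rpois(1L, cfg$background_rate * vol)
    if (m > 0L) {
      coords_list[[length(coords_list) + 1L]] <-
        matrix(runif(m * d, 0, cfg$field_size), ncol = d)
      gene_list[[length(gene_list) + 1L]] <- sample.int(L, m, replace = TRUE)
      cell_list[[length(cell_list) + 1L]] <- rep(-1L, m)
    }
  }

  coords <- do.call(rbind, coords_list)
  # clamp the rare context/noise spot that falls outside the field
  coords <- pmin(pmax(coords, 0), cfg$field_size)
  gene <- genes[unlist(gene_list)]
  spot_cell <- unlist(cell_list)
  spots <- spot_table(coords, gene)
  list(spots = spots,
       truth = list(spot_cell = as.integer(spot_cell),
                    cell_type = cell_type,
                    cell_centers = centers,
                    type_profiles = type_profiles),
       config = cfg)
}

#' Named difficulty presets for the simulator
#'
#' * `easy`: 30 well-separated cells (separation 4 radii), 3 cell types with
#'   spiky gene profiles, 10 genes, ~150 reads per cell, no background — every
#'   stage of the pipeline should recover the cells nearly perfectly.
#' * `medium`: same cells packed tighter (3 radii) with uniform background
#'   noise added.
#' * `hard`: large, sparse, physically *overlapping* cells (separation 1.6
#'   radii): the close neighborhood scale contains too few reads to estimate
#'   a gene composition reliably, while the mid/long scales (2–5 base radii)
#'   aggregate a cell's own reads into a stable type signature.  Geometry
#'   alone cannot split abutting cells here, so this regime separates
#'   multi-scale from single-scale features.
#'
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed integer seed stored in the config.
#' @return A [simulation_config].
#' @export
make_separable_preset <- function(difficulty = c("easy", "medium", "hard"),
                                  seed = 1L) {
  difficulty <- tryCatch(match.arg(difficulty), error = function(e) {
    stop("unknown preset '", difficulty[1L],
         "'; valid presets: easy, medium, hard")
  })
  switch(difficulty,
    easy = simulation_config(
      n_cells = 30L, n_cell_types = 3L, n_genes = 10L,
      mean_reads_per_cell = 150, cell_radius = 15,
      min_center_separation = 60, field_size = 420,
      background_rate = 0, type_profile_concentration = 0.3,
      seed = seed),
    medium = simulation_config(
      n_cells = 30L, n_cell_types = 3L, n_genes = 10L,
      mean_reads_per_cell = 150, cell_radius = 15,
      min_center_separation = 45, field_size = 380,
      background_rate = 2e-4, type_profile_concentration = 0.3,
      seed = seed),
    hard = simulation_config(
      n_cells = 20L, n_cell_types = 3L, n_genes = 24L,
      mean_reads_per_cell = 100, cell_radius = 25,
      min_center_separation = 40, field_size = 280,
      background_rate = 2e-4, type_profile_concentration = 0.3,
      seed = seed))
}
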