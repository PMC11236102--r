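#' Multi-scale neighborhood gene composition (MSNGC)
#'
#' For every spot, counts the gene tags of the surrounding spots inside
#' concentric neighborhoods at several scales (by default radii `R`, `3R`,
#' `5R`).  The result is one `c x L` count matrix per spot (`c` scales,
#' `L` gene tags) describing the local transcriptomic context at increasing
#' reach.  The spot's own gene tag is excluded from its counts: the feature
#' describes the *adjacent* composition, and self-inclusion would add a
#' constant that blunts contrast between spots.
#'
#' Neighborhood geometry: in 2D, a disc of radius `s * base_radius_xy` for
#' scale factor `s`; in 3D, the axis-scaled ellipsoid
#' \deqn{(\Delta x^2 + \Delta y^2)/(s R_{xy})^2 + \Delta z^2/(s R_z)^2 \le 1,}
#' which accommodates the anisotropic axial resolution of imaging-based
#' assays (default radii 10 in x/y, 7 in z).  The boundary is inclusive.
#' Counts are exact (identical to an all-pairs scan).
#'
#' @param spots a [spot_table].
#' @param base_radius_xy base neighborhood radius in the x/y plane
#'   (default 10, in the units of the coordinates).
#' @param base_radius_z base radius along z for 3D data (default 7).
#' @param scale_factors strictly ascending positive multipliers applied to the
#'   base radii; default `c(1, 3, 5)`.
#' @return An object of class `msngc_stack`: a list with `counts` (an
#'   `N x c x L` integer array), `base_radius_xy`, `base_radius_z` and
#'   `scale_factors`.  Along the scale axis counts are monotone non-decreasing
#'   (a larger radius contains the smaller).
#' @examples
#' st <- spot_table(cbind(c(0, 5, 40), c(0, 0, 0)), gene = c("a", "b", "a"))
#' m <- compute_msngc(st, base_radius_xy = 10)
#' m$counts[1, , ]  # spot 2 enters all scales; spot 3 only scale 5R
#' @export
compute_msngc <- function(spots, base_radius_xy = 10, base_radius_z = 7,
                          scale_factors = c(1, 3, 5)) {
  if (base_radius_xy <= 0) stop("base_radius_xy must be positive")
  if (spot_dim(spots) == 3L && base_radius_z <= 0) {
    stop("base_radius_z must be positive for 3D data")
  }
  if (length(scale_factors) < 1L || any(scale_factors <= 0) ||
      is.unsorted(scale_factors, strictly = TRUE)) {
    stop("scale_factors must be strictly ascending and positive")
  }
  n <- n_spots(spots)
  L <- length(spots$gene_names)
  nc <- length(scale_factors)
  counts <- array(0L, dim = c(n, nc, L),
                  dimnames = list(NULL, paste0("scale_", scale_factors),
                                  spots$gene_names))
  stack <- structure(
    list(counts = counts, base_radius_xy = base_radius_xy,
         base_radius_z = base_radius_z, scale_factors = scale_factors),
    class = "msngc_stack")
  if (n == 0L) return(stack)

  # Normalized squared radius q(i,j) such that j is inside the scale-s
  # neighborhood of i iff q <= s^2 (the ellipsoid test divides through by s^2).
  xy <- spots$coords[, 1:2, drop = FALSE] / base_radius_xy
  sq_xy <- rowSums(xy^2)
  if (spot_dim(spots) == 3L) {
    z <- spots$coords[, 3L] / base_radius_z
  } else {
    z <- NULL
  }
  # gene indicator matrix: mask %*% G gives per-spot gene counts
  G <- Matrix::sparseMatrix(i = seq_len(n), j = spots$gene_ids,
                            x = 1, dims = c(n, L))
  s2 <- scale_factors^2
  chunk <- max(1L, min(n, as.integer(2^22 / n)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    q <- outer(sq_xy[idx], sq_xy, "+") -
      2 * tcrossprod(xy[idx, , drop = FALSE], xy)
    if (!is.null(z)) q <- q + outer(z[idx], z, "-")^2
    q[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    for (b in seq_len(nc)) {
      mask <- (q <= s2[b]) * 1
      counts[idx, b, ] <- as.matrix(mask %*% G)
    }
  }
  storage.mode(counts) <- "integer"
  stack$counts <- counts
  stack
}

#' @export
print.msngc_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "msngc_stack: %d spots, %d scales (factors %s), %d gene tags, R_xy=%g\n",
    d[1L], d[2L], paste(x$scale_factors, collapse = "/"), d[3L],
    x$base_radius_xy))
  invisible(x)
}

#' MSNGC correlation between two spots
#'
#' The transcriptomic similarity of two spots is the mean over scales of the
#' per-scale Pearson correlation between their neighborhood gene-composition
#' rows.  A scale at which either row is constant (e.g. all-zero counts for an
#' isolated spot) carries no evidence of association and contributes 0.
#' Averaging over scales keeps the result in `[-1, 1]`, which in turn keeps
#' the fused distance of [st_distance] non-negative.
#'
#' @param m_i,m_j `c x L` count matrices (rows = scales) of the two spots,
#'   e.g. slices `stack$counts[i, , ]`.
#' @return The mean per-scale Pearson correlation, in `[-1, 1]`.
#' @examples
#' m <- rbind(c(1, 2, 0), c(3, 1, 2))
#' msngc_correlation(m, m)  # 1
#' @export
msngc_correlation <- function(m_i, m_j) {
  m_i <- as.matrix(m_i); m_j <- as.matrix(m_j)
  if (!all(dim(m_i) == dim(m_j))) {
    stop("MSNGC matrices must share their c x L shape")
  }
  nc <- nrow(m_i)
  if (nc < 1L) stop("need at least one scale")
  rho <- 0
  for (b in seq_len(nc)) {
    a <- m_i[b, ] - mean(m_i[b, ])
    c_ <- m_j[b, ] - mean(m_j[b, ])
    va <- sum(a^2); vb <- sum(c_^2)
    if (va > 0 && vb > 0) rho <- rho + sum(a * c_) / sqrt(va * vb)
  }
  rho / nc
}

# Per-scale standardized feature rows: center each spot's length-L row and
# scale to unit norm; zero-variance rows become zero rows so their dot product
# (the per-scale correlation) is 0.  Returns a list of N x L matrices.
msngc_standardize <- function(stack) {
  d <- dim(stack$counts)
  lapply(seq_len(d[2L]), function(b) {
    m <- matrix(as.numeric(stack$counts[, b, ]), nrow = d[1L])
    m <- m - rowMeans(m)
    nrm <- sqrt(rowSums(m^2))
    nz <- nrm > 0
    m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
    m[!nz, ] <- 0
    m
  })
}

# Dense N x N matrix of mean per-scale Pearson correlations.
msngc_rho_matrix <- function(stack) {
  zs <- msngc_standardize(stack)
  rho <- Reduce(`+`, lapply(zs, tcrossprod))
  rho / length(zs)
}

# Dense N x N Manhattan distance matrix on physical coordinates.
manhattan_matrix <- function(coords) {
  n <- nrow(coords)
  d <- matrix(0, n, n)
  for (j in seq_len(ncol(coords))) {
    d <- d + abs(outer(coords[, j], coords[, j], "-"))
  }
  d
}

#' Spatial-transcriptomic (ST) distance
#'
#' Fuses physical location and local transcriptomic context into one
#' dissimilarity: the Manhattan distance between two spots' coordinates is
#' scaled by one minus their MSNGC correlation,
#' \deqn{D(i, j) = d_{\mathrm{Manhattan}}(i, j) \times (1 - \rho_{MSNGC}(i, j)).}
#' Spots that are physically close *and* share neighborhood gene composition
#' get a small distance; identical composition (correlation 1) collapses the
#' distance to 0 regardless of separation.  The measure is symmetric and
#' non-negative (the scaling factor lies in `[0, 2]`) but need not satisfy the
#' triangle inequality, which the downstream manifold construction does not
#' require.
#'
#' @param spots a [spot_table].
#' @param msngc the matching [compute_msngc] stack.
#' @param i,j spot indices (1-based).
#' @return A non-negative scalar; `st_distance(spots, msngc, i, i)` is 0.
#' @seealso [st_distance_matrix] for all pairs at once.
#' @export
st_distance <- function(spots, msngc, i, j) {
  n <- n_spots(spots)
  if (i < 1L || i > n || j < 1L || j > n) stop("spot index out of bounds")
  if (i == j) return(0)
  rho <- msngc_correlation(msngc$counts[i, , , drop = TRUE],
                           msngc$counts[j, , , drop = TRUE])
  sum(abs(spots$coords[i, ] - spots$coords[j, ])) * (1 - rho)
}

#' All-pairs ST distance matrix
#'
#' @inheritParams st_distance
#' @return A dense symmetric `N x N` matrix of ST distances with zero
#'   diagonal.  Memory is `O(N^2)`; intended for the exact k-NN path.
#' @export
st_distance_matrix <- function(spots, msngc) {
  d <- manhattan_matrix(spots$coords) * (1 - msngc_rho_matrix(msngc))
  # numerical guard: correlation can exceed 1 by rounding
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Export MSNGC features in long format
#'
#' Debug/inspection export: one row per (spot, scale, gene) with a non-zero
#' count by default.
#'
#' @param spots a [spot_table].
#' @param msngc the matching [compute_msngc] stack.
#' @param drop_zero drop zero counts (default `TRUE`).
#' @return A `data.frame` with columns `spot_id`, `scale`, `gene`, `count`.
#' @export
msngc_long <- function(spots, msngc, drop_zero = TRUE) {
  d <- dim(msngc$counts)
  df <- data.frame(
    spot_id = rep(spots$spot_ids, times = d[2L] * d[3L]),
    scale = rep(rep(msngc$scale_factors, each = d[1L]), times = d[3L]),
    gene = rep(spots$gene_names, each = d[1L] * d[2L]),
    count = as.vector(msngc$counts))
  if (drop_zero) df <- df[df$count > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df
}
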