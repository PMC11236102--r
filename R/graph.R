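#' k-nearest-neighbor graph under the ST distance
#'
#' Finds, for every spot, its `k` nearest *other* spots under the fused
#' spatial-transcriptomic distance of [st_distance].  Below `exact_cutoff`
#' spots the search is exact (full distance matrix + per-row sort); above it a
#' seeded NN-descent refinement is used, whose neighbor lists converge to the
#' exact ones on the fields it is tested on.  Ties are broken by the lower
#' spot index, so results are deterministic.
#'
#' @param spots a [spot_table].
#' @param msngc the matching [compute_msngc] stack.
#' @param k number of neighbors, `2 <= k < N`.
#' @param exact_cutoff largest `N` for which the exact path is used
#'   (default 20000).
#' @param seed integer seed for the NN-descent path.
#' @return A list with `idx` (`N x k` integer matrix of neighbor indices) and
#'   `dist` (`N x k` ST distances, ascending within each row).
#' @export
knn_graph <- function(spots, msngc, k, exact_cutoff = 20000L, seed = 1L) {
  n <- n_spots(spots)
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (",
                   n, ")")
  if (k < 2L) stop("k must be at least 2")
  if (n <= exact_cutoff) {
    d <- st_distance_matrix(spots, msngc)
    knn_from_dense(d, k)
  } else {
    knn_nn_descent(spots, msngc, k, seed = seed)
  }
}

# exact k-NN from a dense distance matrix; ties by ascending index
knn_from_dense <- function(d, k) {
  n <- nrow(d)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    o <- order(di, seq_len(n))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- di[o]
  }
  list(idx = idx, dist = dst)
}

# NN-descent: start from random neighbor lists and repeatedly propose
# neighbors-of-neighbors (and reverse edges), keeping the k best per vertex.
# Distances are evaluated lazily from the standardized MSNGC rows, so no
# N x N matrix is formed.
knn_nn_descent <- function(spots, msngc, k, seed = 1L, max_iter = 30L,
                           tol_frac = 1e-3) {
  n <- n_spots(spots)
  zs <- msngc_standardize(msngc)
  coords <- spots$coords
  pair_dist <- function(i, j) {
    rho <- rowSums(vapply(zs, function(z) {
      rowSums(z[i, , drop = FALSE] * z[j, , drop = FALSE])
    }, numeric(length(i)))) / length(zs)
    man <- rowSums(abs(coords[i, , drop = FALSE] - coords[j, , drop = FALSE]))
    pmax(man * (1 - rho), 0)
  }
  set.seed(seed)
  idx <- t(vapply(seq_len(n), function(i) {
    sort(sample(seq_len(n)[-i], k))
  }, integer(k)))
  dst <- matrix(0, n, k)
  for (j in seq_len(k)) dst[, j] <- pair_dist(seq_len(n), idx[, j])
  for (i in seq_len(n)) {
    o <- order(dst[i, ], idx[i, ])
    idx[i, ] <- idx[i, o]; dst[i, ] <- dst[i, o]
  }
  pair_cap <- 4096L
  for (iter in seq_len(max_iter)) {
    # local join: vertices sharing a (forward or reverse) neighbor propose
    # each other; plus a few uniform random probes to escape local optima
    rev_list <- split(rep(seq_len(n), times = k), as.vector(idx))
    join_i <- vector("list", n)
    join_j <- vector("list", n)
    for (u in seq_len(n)) {
      g <- unique(c(idx[u, ], rev_list[[as.character(u)]]))
      np <- length(g)^2
      if (np > pair_cap) {
        ii <- sample(g, pair_cap, replace = TRUE)
        jj <- sample(g, pair_cap, replace = TRUE)
      } else {
        ii <- rep(g, times = length(g))
        jj <- rep(g, each = length(g))
      }
      join_i[[u]] <- ii
      join_j[[u]] <- jj
    }
    n_rand <- 4L
    cand_i <- c(unlist(join_i), rep(seq_len(n), times = n_rand))
    cand_j <- c(unlist(join_j), sample.int(n, n * n_rand, replace = TRUE))
    keep <- cand_i != cand_j
    cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
    cd <- pair_dist(cand_i, cand_j)
    updated <- 0L
    # per-vertex merge of current list and candidates, keep k best
    by_i <- split(seq_along(cand_i), cand_i)
    for (nm in names(by_i)) {
      i <- as.integer(nm)
      s <- by_i[[nm]]
      jj <- c(idx[i, ], cand_j[s])
      dd <- c(dst[i, ], cd[s])
      dup <- !duplicated(jj)
      jj <- jj[dup]; dd <- dd[dup]
      o <- order(dd, jj)[seq_len(k)]
      new_idx <- jj[o]; new_dst <- dd[o]
      if (!identical(new_idx, idx[i, ])) updated <- updated + 1L
      idx[i, ] <- new_idx; dst[i, ] <- new_dst
    }
    if (updated == 0L || (iter > 5L && updated <= tol_frac * n)) break
  }
  list(idx = idx, dist = dst)
}

#' Calibrate the per-spot kernel bandwidth
#'
#' For a spot with sorted neighbor distances \eqn{D_1 \le \dots \le D_k}, the
#' offset \eqn{\delta} is the distance to the nearest neighbor and the
#' bandwidth \eqn{\sigma} is chosen so that the neighbor weights sum to the
#' target connectivity:
#' \deqn{\sum_{j=1}^{k} \exp(-\max\{0, D_j - \delta\}/\sigma) = \log_2(k).}
#' The sum is monotone increasing in \eqn{\sigma}, so the root is found by
#' bisection.  When every distance equals \eqn{\delta} the sum is identically
#' `k` and the target is unattainable; \eqn{\sigma} is then pinned at its
#' lower search bound and the row is flagged.
#'
#' @param knn_dists_row ascending numeric vector of the spot's `k` neighbor
#'   distances.
#' @param k number of neighbors (defaults to the row length).
#' @param tol absolute tolerance on the weight-sum residual (default 1e-5).
#' @return A list with `delta`, `sigma`, `flag` (TRUE when the target was
#'   unattainable) and `residual` (achieved sum minus the target).
#' @export
calibrate_bandwidth <- function(knn_dists_row, k = length(knn_dists_row),
                                tol = 1e-5) {
  if (is.unsorted(knn_dists_row)) stop("neighbor distances must be ascending")
  if (k < 2L) stop("k must be at least 2")
  cal <- calibrate_bandwidths(matrix(knn_dists_row, nrow = 1L), tol = tol)
  list(delta = cal$delta[1L], sigma = cal$sigma[1L], flag = cal$flag[1L],
       residual = cal$residual[1L])
}

# Vectorized bandwidth calibration over all rows of an N x k distance matrix.
calibrate_bandwidths <- function(knn_dists, tol = 1e-5, max_iter = 64L) {
  n <- nrow(knn_dists); k <- ncol(knn_dists)
  target <- log2(k)
  delta <- knn_dists[, 1L]
  e <- pmax(knn_dists - delta, 0)          # clamped excess distances
  wsum <- function(sigma) rowSums(exp(-e / sigma))
  sigma_min <- pmax(1e-3 * rowMeans(knn_dists), .Machine$double.eps)
  flag <- wsum(sigma_min) > target + tol   # unattainably tied rows
  lo <- sigma_min
  hi <- pmax(sigma_min * 2, e[, k])
  for (it in seq_len(max_iter)) {
    need <- !flag & wsum(hi) < target
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    s <- wsum(mid)
    up <- s < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  sigma <- (lo + hi) / 2
  sigma[flag] <- sigma_min[flag]
  list(delta = delta, sigma = sigma, flag = flag,
       residual = wsum(sigma) - target)
}

#' Directed neighbor weights
#'
#' Converts calibrated neighbor distances into edge weights
#' \eqn{w_{ij} = \exp(-\max\{0, D_{ij} - \delta_i\}/\sigma_i) \in (0, 1]}.
#' The nearest neighbor always receives weight exactly 1 (its excess distance
#' is 0); the clamp guards against unsorted input.
#'
#' @param knn_dists `N x k` neighbor-distance matrix.
#' @param delta length-`N` per-spot offsets.
#' @param sigma length-`N` per-spot bandwidths.
#' @return `N x k` matrix of weights in `(0, 1]`.
#' @export
directed_weights <- function(knn_dists, delta, sigma) {
  exp(-pmax(knn_dists - delta, 0) / sigma)
}

#' Fuzzy union of directed weights into a symmetric adjacency
#'
#' Combines the two directed weights of every spot pair by the probabilistic
#' (fuzzy-set) union \eqn{A_{ij} = w_{ij} + w_{ji} - w_{ij} w_{ji}}, with a
#' missing direction treated as weight 0 (so one-sided edges reduce to their
#' single weight).  The result is symmetric with entries in `[0, 1]` and a
#' zero diagonal, and is monotone in each directed weight.
#'
#' @param weights `N x k` matrix of directed weights in `[0, 1]`.
#' @param idx matching `N x k` neighbor index matrix.
#' @param n number of vertices (defaults to `nrow(weights)`).
#' @return A sparse symmetric `n x n` adjacency matrix (`Matrix::dgCMatrix`).
#' @export
fuzzy_union <- function(weights, idx, n = nrow(weights)) {
  k <- ncol(weights)
  w <- Matrix::sparseMatrix(i = rep(seq_len(nrow(weights)), times = k),
                            j = as.vector(idx), x = as.vector(weights),
                            dims = c(n, n))
  wt <- Matrix::t(w)
  a <- w + wt - w * wt
  Matrix::diag(a) <- 0
  Matrix::drop0(a)
}

#' Spectral initialization of the embedding
#'
#' Computes initial low-dimensional coordinates from the fuzzy adjacency by
#' taking eigenvectors of the symmetric normalized graph Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}}: eigenvectors `2..d+1` by ascending
#' eigenvalue (the first, trivial one is skipped), scaled so the largest
#' absolute coordinate is 10.  Signs are fixed by making each column's
#' largest-magnitude entry positive, so the result is deterministic.  Up to
#' `dense_cutoff` vertices a dense eigendecomposition is used; above it, a
#' deterministic seeded subspace (orthogonal) iteration with sparse
#' matrix-vector products.  Vertices with zero degree receive small seeded
#' random coordinates.
#'
#' @param a symmetric non-negative adjacency (sparse or dense).
#' @param d embedding dimension.
#' @param seed integer seed (isolated-vertex placement and the iterative
#'   solver's start matrix).
#' @param dense_cutoff largest `N` for the dense eigensolver (default 2048).
#' @param n_iter subspace-iteration count for the large-`N` path.
#' @return `N x d` coordinate matrix.
#' @export
spectral_init <- function(a, d, seed = 1L, dense_cutoff = 2048L,
                          n_iter = 200L) {
  n <- nrow(a)
  if (d < 1L) stop("d must be at least 1")
  deg <- Matrix::rowSums(a)
  live <- which(deg > 0)
  m <- length(live)
  if (d + 1L > max(m, 1L)) stop("d + 1 eigenpairs are not computable for ",
                                m, " connected vertices")
  coords <- matrix(0, n, d)
  set.seed(seed)
  iso <- setdiff(seq_len(n), live)
  if (length(iso)) coords[iso, ] <- matrix(runif(length(iso) * d, -1, 1),
                                           ncol = d)
  asub <- a[live, live, drop = FALSE]
  dis <- 1 / sqrt(deg[live])
  # normalized adjacency Dn = D^{-1/2} A D^{-1/2}; smallest eigenpairs of the
  # normalized Laplacian are its largest ones
  dn <- Matrix::Diagonal(x = dis) %*% asub %*% Matrix::Diagonal(x = dis)
  if (m <= dense_cutoff) {
    es <- eigen(as.matrix(Matrix::forceSymmetric(dn)), symmetric = TRUE)
    vec <- es$vectors[, seq_len(d + 1L), drop = FALSE]  # descending eigenvalue
  } else {
    vec <- subspace_topvecs(dn, d + 1L, n_iter = n_iter)
  }
  v <- vec[, -1L, drop = FALSE]  # drop the trivial top eigenvector
  for (j in seq_len(d)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) v[, j] <- -v[, j]
  }
  coords[live, ] <- v
  mx <- max(abs(coords))
  if (mx > 0) coords <- coords * (10 / mx)
  coords
}

# Deterministic subspace iteration for the top-p eigenvectors (by algebraic
# eigenvalue) of a symmetric matrix with spectrum in [-1, 1]: iterate on
# (M + I) so the target eigenvalues are the largest in magnitude, then
# Rayleigh-Ritz.  Start matrix comes from the current RNG state.
subspace_topvecs <- function(m, p, n_iter = 200L) {
  n <- nrow(m)
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  for (it in seq_len(n_iter)) {
    y <- as.matrix(m %*% q) + q
    q <- qr.Q(qr(y))
  }
  # Rayleigh-Ritz: sort Ritz values descending
  h <- crossprod(q, as.matrix(m %*% q))
  h <- (h + t(h)) / 2
  es <- eigen(h, symmetric = TRUE)
  q %*% es$vectors
}
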