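#' Density-based clustering (DBSCAN)
#'
#' From-scratch DBSCAN on Euclidean distance.  A point is a *core* point when
#' its eps-ball (boundary inclusive, the point itself counted) contains at
#' least `min_samples` points; clusters are the connected components of
#' mutually reachable core points plus their density-reachable border points;
#' everything else is noise (`-1`).  Points are scanned in ascending index
#' order and border points reachable from several clusters go to the cluster
#' formed first, so labels are deterministic.
#'
#' Note that `min_samples = 1` makes every point a core point, which disables
#' noise detection entirely.
#'
#' @param points `N x d` numeric coordinate matrix.
#' @param eps neighborhood radius, `> 0`.
#' @param min_samples core-point threshold, `>= 1`, counting the point itself.
#' @return Integer vector of labels: cluster ids `0..C-1`, noise `-1`.
#' @examples
#' pts <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10))
#' dbscan_labels(pts, eps = 1.5, min_samples = 3)
#' @export
dbscan_labels <- function(points, eps, min_samples) {
  points <- as.matrix(points)
  if (eps <= 0) stop("eps must be positive")
  if (min_samples < 1L) stop("min_samples must be at least 1")
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  nbrs <- eps_neighbors(points, eps)
  n_nbr <- lengths(nbrs) + 1L            # self-inclusive count
  core <- n_nbr >= min_samples
  labels <- rep(-1L, n)
  visited <- logical(n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (!core[i]) next                   # may be claimed later as border
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]; qpos <- qpos + 1L
      if (labels[j] == -1L) labels[j] <- cl   # border or new member
      if (!visited[j]) {
        visited[j] <- TRUE
        if (core[j]) queue <- c(queue, nbrs[[j]])
      }
    }
  }
  labels
}

# ascending-index neighbor lists within eps (self excluded), chunked
eps_neighbors <- function(points, eps, chunk = 1024L) {
  n <- nrow(points)
  sq <- rowSums(points^2)
  out <- vector("list", n)
  eps2 <- eps^2 * (1 + 1e-12)            # inclusive boundary, rounding guard
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(points[idx, , drop = FALSE], points)
    for (r in seq_along(idx)) {
      i <- idx[r]
      nb <- which(d2[r, ] <= eps2)
      out[[i]] <- nb[nb != i]
    }
  }
  out
}

#' Default DBSCAN radius from the embedding
#'
#' k-dist heuristic: a multiple of a high percentile of the distance to the
#' `min_samples`-th nearest neighbor over all embedded points.  The embedding
#' stage compresses cells into blobs whose internal point spacing is an order
#' of magnitude below the blob separation, so any radius above the k-dist
#' tail and below the blob separation works; the default
#' `3 x 99th percentile` sits in that window (bridging low-density necks
#' inside elongated cells) while still leaving genuinely isolated points as
#' noise.
#'
#' @param points `N x d` coordinates.
#' @param min_samples neighbor rank used for the k-dist curve (default 4,
#'   matching the pipeline's DBSCAN default).
#' @param prob percentile of the k-dist curve (default 0.99).
#' @param mult safety multiplier above the percentile (default 3).
#' @return A positive scalar usable as `eps`.
#' @export
default_eps <- function(points, min_samples = 4L, prob = 0.99, mult = 3) {
  points <- as.matrix(points)
  kth <- max(1L, as.integer(min_samples))
  n <- nrow(points)
  if (n <= kth) stop("too few points for the eps heuristic")
  sq <- rowSums(points^2)
  kd <- numeric(n)
  chunk <- 1024L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(points[idx, , drop = FALSE], points)
    d2[cbind(seq_along(idx), idx)] <- Inf
    kd[idx] <- apply(d2, 1L, function(v) sqrt(max(sort(v)[kth], 0)))
  }
  e <- mult * as.numeric(stats::quantile(kd, prob, names = FALSE))
  if (e <= 0) e <- max(mult * kd[kd > 0], 1e-8)  # many coincident points
  e
}

#' Representative center spot of each cluster
#'
#' For every cluster, the member closest (Euclidean) to the cluster's
#' coordinate mean — a medoid-to-centroid rule; ties go to the lowest index.
#'
#' @param points `N x d` coordinates (clustering space).
#' @param labels integer labels from [dbscan_labels]; `-1` = noise.
#' @return Named integer vector: one point index per cluster id (names are
#'   the cluster ids).
#' @export
cluster_centers <- function(points, labels) {
  points <- as.matrix(points)
  ids <- sort(unique(labels[labels >= 0L]))
  if (!length(ids)) {
    stop("all points are noise; decrease min_samples or increase eps")
  }
  centers <- vapply(ids, function(cl) {
    members <- which(labels == cl)
    ctr <- colMeans(points[members, , drop = FALSE])
    d2 <- colSums((t(points[members, , drop = FALSE]) - ctr)^2)
    members[which.min(d2)]            # which.min takes the first = lowest index
  }, integer(1))
  names(centers) <- ids
  centers
}

#' Pipeline configuration
#'
#' One document holding every stage's parameters.  Defaults follow the
#' method's recommended settings: neighborhood radii 10 (x/y) and 7 (z),
#' scale factors 1/3/5, `k = 50` graph neighbors, initial learning rate 1.0,
#' epochs chosen by data-set size, and DBSCAN `min_samples = 4` (the
#' originally stated default of 1 turns every point into a core point and
#' disables noise detection; see [dbscan_labels]).  `eps = NULL` selects the
#' knee heuristic of [default_eps] on the embedding.
#'
#' @param filter_quantile quantile for [filter_outliers] (`NULL` disables
#'   filtering).
#' @param filter_threshold absolute outlier threshold overriding the quantile.
#' @param radius_xy,radius_z,scale_factors MSNGC neighborhood geometry, see
#'   [compute_msngc].
#' @param k graph neighbors, see [knn_graph].
#' @param embedding an [embedding_config].
#' @param eps DBSCAN radius (`NULL` = knee heuristic).
#' @param min_samples DBSCAN core threshold.
#' @param refine_rounds center-based refinement rounds after the first
#'   clustering (default 1).
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(filter_quantile = 0.99,
                                filter_threshold = NULL,
                                radius_xy = 10, radius_z = 7,
                                scale_factors = c(1, 3, 5),
                                k = 50L,
                                embedding = embedding_config(),
                                eps = NULL, min_samples = 4L,
                                refine_rounds = 1L, seed = 1L) {
  stopifnot(is.null(eps) || eps > 0, min_samples >= 1L, refine_rounds >= 0L)
  structure(list(filter_quantile = filter_quantile,
                 filter_threshold = filter_threshold,
                 radius_xy = radius_xy, radius_z = radius_z,
                 scale_factors = scale_factors, k = as.integer(k),
                 embedding = embedding, eps = eps,
                 min_samples = as.integer(min_samples),
                 refine_rounds = as.integer(refine_rounds),
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Refine the fuzzy graph with cluster-center edges
#'
#' After a first clustering, the pairwise ST distances among the cluster
#' *center* spots are converted to fuzzy edge weights with the same
#' kernel/bandwidth machinery (k capped at one less than the number of
#' centers) and folded into the existing adjacency by fuzzy union.  The
#' spectral initialization and the embedding optimization are then rerun on
#' the augmented graph.  With fewer than 3 clusters the refinement is skipped
#' with a warning.
#'
#' @param spots filtered [spot_table] backing the graph.
#' @param msngc matching MSNGC stack.
#' @param a_mat current fuzzy adjacency.
#' @param centers center spot indices from [cluster_centers].
#' @param config a [segmentation_config].
#' @param seed seed for the re-initialization and re-optimization.
#' @return A list with the augmented adjacency `a_mat` and the re-optimized
#'   `embedding` (`NULL` when skipped).
#' @export
refine_with_centers <- function(spots, msngc, a_mat, centers, config,
                                seed = config$seed) {
  centers <- as.integer(centers)
  nc <- length(centers)
  if (nc < 3L) {
    warning("center refinement skipped: only ", nc, " clusters")
    return(list(a_mat = a_mat, embedding = NULL))
  }
  sub_spots <- spots[centers]
  sub_counts <- msngc$counts[centers, , , drop = FALSE]
  sub_stack <- structure(list(counts = sub_counts,
                              base_radius_xy = msngc$base_radius_xy,
                              base_radius_z = msngc$base_radius_z,
                              scale_factors = msngc$scale_factors),
                         class = "msngc_stack")
  kc <- min(config$k, nc - 1L)
  d <- st_distance_matrix(sub_spots, sub_stack)
  kn <- knn_from_dense(d, kc)
  if (kc >= 2L) {
    cal <- calibrate_bandwidths(kn$dist)
    w <- directed_weights(kn$dist, cal$delta, cal$sigma)
  } else {
    w <- matrix(1, nc, 1L)
  }
  a_cen_small <- fuzzy_union(w, kn$idx, n = nc)
  # lift center-center edges into the full index space, fuzzy-union with A
  tri <- methods::as(methods::as(a_cen_small, "generalMatrix"), "TsparseMatrix")
  a_cen <- Matrix::sparseMatrix(i = centers[tri@i + 1L],
                                j = centers[tri@j + 1L], x = tri@x,
                                dims = dim(a_mat))
  a_new <- a_mat + a_cen - a_mat * a_cen
  Matrix::diag(a_new) <- 0
  a_new <- Matrix::drop0(a_new)
  init <- spectral_init(a_new, config$embedding$d, seed = seed)
  cfg <- config$embedding
  cfg$seed <- seed
  emb <- optimize_embedding(a_new, init, cfg)
  list(a_mat = a_new, embedding = emb)
}

#' End-to-end cell segmentation of a spot table
#'
#' Runs the full pipeline: outlier filtering, MSNGC features, ST-distance
#' k-NN graph, bandwidth calibration, fuzzy union, spectral initialization,
#' embedding optimization, DBSCAN, then (optionally, per
#' `config$refine_rounds`) cluster-center graph refinement followed by
#' re-embedding and re-clustering.  Labels are reported over the *original*
#' spot index space; spots removed by the outlier filter are labeled `-1`.
#' The run is deterministic given `config$seed`.
#'
#' @param spots a [spot_table].
#' @param config a [segmentation_config].
#' @return An object of class `segmentation_result`: list with
#'   * `labels`: per-input-spot integer labels (`0..C-1`, noise/filtered `-1`),
#'   * `n_clusters`: number of clusters,
#'   * `centers`: per-cluster representative spot index (original space),
#'   * `embedding`: the final [optimize_embedding] result over kept spots,
#'   * `kept`: logical mask of spots that survived filtering,
#'   * `eps_used`, `params_used`.
#' @examples
#' \donttest{
#' sim <- simulate_spots(make_separable_preset("easy", seed = 1))
#' res <- segment(sim$spots, segmentation_config(seed = 1))
#' res$n_clusters
#' }
#' @export
segment <- function(spots, config = segmentation_config()) {
  n0 <- n_spots(spots)
  empty <- function() {
    structure(list(labels = integer(0), n_clusters = 0L,
                   centers = integer(0), embedding = NULL,
                   kept = logical(0), eps_used = NA_real_,
                   params_used = config),
              class = "segmentation_result")
  }
  if (n0 == 0L) return(empty())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  kept <- rep(TRUE, n0)
  work <- spots
  if (!is.null(config$filter_threshold) || !is.null(config$filter_quantile)) {
    if (n0 >= 2L) {
      fl <- stage("filter_outliers",
                  filter_outliers(spots, threshold = config$filter_threshold,
                                  quantile = if (is.null(config$filter_quantile))
                                    0.99 else config$filter_quantile))
      kept <- fl$kept
      work <- fl$spots
    }
  }
  n <- n_spots(work)
  if (n < 3L) stop("too few spots remain after filtering (", n, ")")
  msngc <- stage("compute_msngc",
                 compute_msngc(work, config$radius_xy, config$radius_z,
                               config$scale_factors))
  k <- min(config$k, n - 1L)
  kn <- stage("knn_graph", knn_graph(work, msngc, k, seed = config$seed))
  cal <- stage("calibrate_bandwidth", calibrate_bandwidths(kn$dist))
  w <- directed_weights(kn$dist, cal$delta, cal$sigma)
  a_mat <- stage("fuzzy_union", fuzzy_union(w, kn$idx, n = n))
  init <- stage("spectral_init",
                spectral_init(a_mat, config$embedding$d, seed = config$seed))
  cfg <- config$embedding
  cfg$seed <- config$seed
  emb <- stage("optimize_embedding", optimize_embedding(a_mat, init, cfg))
  eps <- if (is.null(config$eps)) default_eps(emb$coords, config$min_samples) else config$eps
  labels <- stage("dbscan", dbscan_labels(emb$coords, eps, config$min_samples))
  for (round in seq_len(config$refine_rounds)) {
    if (!any(labels >= 0L)) break
    centers <- cluster_centers(emb$coords, labels)
    ref <- stage("refine_with_centers",
                 refine_with_centers(work, msngc, a_mat, centers, config,
                                     seed = config$seed + round))
    if (is.null(ref$embedding)) break
    a_mat <- ref$a_mat
    emb <- ref$embedding
    eps <- if (is.null(config$eps)) default_eps(emb$coords, config$min_samples) else config$eps
    labels <- stage("dbscan", dbscan_labels(emb$coords, eps,
                                            config$min_samples))
  }
  centers_kept <- if (any(labels >= 0L)) {
    cluster_centers(emb$coords, labels)
  } else integer(0)
  full_labels <- rep(-1L, n0)
  full_labels[kept] <- labels
  kept_idx <- which(kept)
  structure(list(labels = full_labels,
                 n_clusters = length(unique(labels[labels >= 0L])),
                 centers = kept_idx[centers_kept],
                 embedding = emb,
                 kept = kept,
                 eps_used = eps,
                 params_used = config),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "segmentation_result: %d spots, %d clusters, %d noise/filtered (eps %.4g)\n",
    n, x$n_clusters, sum(x$labels == -1L), x$eps_used))
  invisible(x)
}
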