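#' Clustering evaluation metrics
#'
#' Segmentation quality is scored against per-spot ground-truth cell labels
#' with three standard external/internal metrics implemented from their
#' defining formulas: the adjusted Rand index (contingency-table form), the
#' normalized mutual information `2 MI / (H(Y) + H(C))`, and the mean
#' silhouette coefficient.
#'
#' Noise handling: by default, spots predicted as noise (`-1`) and spots whose
#' true label is `-1` (e.g. simulated background) are excluded before
#' scoring; with `noise = "cluster"` predicted noise is kept as a cluster of
#' its own (true `-1` is always excluded).
#'
#' @param labels_true,labels_pred equal-length integer label vectors.
#' @param noise `"exclude"` (default) or `"cluster"`, see Details.
#' @return `adjusted_rand_index`: a scalar `<= 1`; 1 for identical
#'   partitions, about 0 for independent ones, negative below chance.
#' @name metrics
NULL

# shared preprocessing: drop excluded spots, check size
metric_pair <- function(labels_true, labels_pred, noise = c("exclude", "cluster")) {
  noise <- match.arg(noise)
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length")
  }
  keep <- labels_true != -1L
  if (noise == "exclude") keep <- keep & labels_pred != -1L
  lt <- labels_true[keep]
  lp <- labels_pred[keep]
  if (length(lt) < 2L) {
    stop("fewer than 2 spots remain after noise exclusion")
  }
  list(true = lt, pred = lp)
}

#' @rdname metrics
#' @export
adjusted_rand_index <- function(labels_true, labels_pred,
                                noise = c("exclude", "cluster")) {
  pr <- metric_pair(labels_true, labels_pred, noise)
  ct <- table(pr$true, pr$pred)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' @rdname metrics
#' @export
normalized_mutual_info <- function(labels_true, labels_pred,
                                   noise = c("exclude", "cluster")) {
  pr <- metric_pair(labels_true, labels_pred, noise)
  ct <- table(pr$true, pr$pred)
  n <- sum(ct)
  pij <- ct / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  }
  h_true <- ent(pi_)
  h_pred <- ent(p_j)
  if (h_true + h_pred == 0) return(1)    # both single-label: identical
  outer_p <- outer(pi_, p_j)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  if (mi <= 0) return(0)
  2 * mi / (h_true + h_pred)
}

#' Mean silhouette coefficient
#'
#' Per point, `s_i = (b_i - a_i)/max(a_i, b_i)` where `a_i` is the mean
#' distance to the other members of its own cluster and `b_i` the smallest
#' mean distance to any other cluster; singleton clusters score 0 by
#' convention.  Computed with Euclidean distance, by default on the embedding
#' coordinates (the clustering space); pass physical coordinates to score in
#' tissue space instead.
#'
#' @param points `N x d` numeric coordinates.
#' @param labels integer cluster labels; `-1` (noise) points are dropped.
#' @return Mean silhouette over the scored points, in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(points, labels) {
  points <- as.matrix(points)
  keep <- labels != -1L
  points <- points[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- unique(labels)
  if (length(ids) < 2L) {
    stop("silhouette needs at least 2 clusters")
  }
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[as.character(li)]] == 1L) {
      s[i] <- 0
      next
    }
    mean_by <- tapply(d[i, ], labels, sum)
    own <- as.character(li)
    a_i <- mean_by[[own]] / (sizes[[own]] - 1L)   # exclude self (d=0 in sum)
    others <- setdiff(names(mean_by), own)
    b_i <- min(unlist(mean_by[others]) / as.numeric(sizes[others]))
    m <- max(a_i, b_i)
    s[i] <- if (m > 0) (b_i - a_i) / m else 0
  }
  mean(s)
}

#' Score a segmentation against ground truth
#'
#' Convenience wrapper returning all three metrics at once.
#'
#' @param labels_true,labels_pred per-spot labels (`-1` = background/noise).
#' @param points optional `N x d` coordinates for the silhouette (typically
#'   the embedding of the scored spots); silhouette is `NA` when omitted.
#' @param noise noise handling, see [metrics].
#' @return Named list `ari`, `nmi`, `sc`.
#' @export
evaluate_segmentation <- function(labels_true, labels_pred, points = NULL,
                                  noise = c("exclude", "cluster")) {
  noise <- match.arg(noise)
  out <- list(
    ari = adjusted_rand_index(labels_true, labels_pred, noise),
    nmi = normalized_mutual_info(labels_true, labels_pred, noise),
    sc = NA_real_)
  if (!is.null(points)) {
    points <- as.matrix(points)
    if (nrow(points) != length(labels_pred)) {
      stop("points and labels_pred disagree on N")
    }
    pred <- labels_pred
    if (noise == "exclude") pred[labels_true == -1L] <- -1L
    n_cl <- length(unique(pred[pred != -1L]))
    if (n_cl >= 2L) out$sc <- silhouette_coefficient(points, pred)
  }
  out
}
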