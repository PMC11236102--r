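# Independent brute-force oracles used across the suite.  Each one is a
# deliberately naive re-derivation from first principles (all-pairs loops,
# contingency tables, direct entropy sums) and never calls the package's own
# implementation of the quantity it checks.

# all-pairs neighborhood gene counts (disc in 2D, axis-scaled ellipsoid in
# 3D); one explicit distance evaluation per (i, j, scale), vectorized over j
oracle_msngc <- function(spots, rxy, rz, scales) {
  n <- n_spots(spots)
  L <- length(spots$gene_names)
  counts <- array(0L, dim = c(n, length(scales), L))
  for (i in seq_len(n)) {
    dxy2 <- (spots$coords[, 1] - spots$coords[i, 1])^2 +
      (spots$coords[, 2] - spots$coords[i, 2])^2
    for (b in seq_along(scales)) {
      s <- scales[b]
      inside <- if (spot_dim(spots) == 2L) {
        dxy2 <= (s * rxy)^2
      } else {
        dz2 <- (spots$coords[, 3] - spots$coords[i, 3])^2
        dxy2 / (s * rxy)^2 + dz2 / (s * rz)^2 <= 1
      }
      inside[i] <- FALSE
      counts[i, b, ] <- tabulate(spots$gene_ids[inside], L)
    }
  }
  counts
}

# scalar mean-of-per-scale Pearson via direct covariance/variance sums
oracle_rho <- function(m_i, m_j) {
  acc <- 0
  for (b in seq_len(nrow(m_i))) {
    x <- m_i[b, ]; y <- m_j[b, ]
    vx <- sum((x - mean(x))^2); vy <- sum((y - mean(y))^2)
    if (vx > 0 && vy > 0) {
      acc <- acc + sum((x - mean(x)) * (y - mean(y))) / sqrt(vx * vy)
    }
  }
  acc / nrow(m_i)
}

# dense evaluation of the fuzzy union over all ordered pairs
oracle_fuzzy_union <- function(weights, idx, n) {
  w <- matrix(0, n, n)
  for (i in seq_len(nrow(weights))) {
    for (col in seq_len(ncol(weights))) {
      w[i, idx[i, col]] <- weights[i, col]
    }
  }
  a <- w + t(w) - w * t(w)
  diag(a) <- 0
  a
}

# double-loop cross-entropy over ordered pairs
oracle_ce <- function(a_mat, coords, a, b, eps = 1e-12) {
  p <- as.matrix(a_mat)
  n <- nrow(coords)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      q <- 1 / (1 + a * sum((coords[i, ] - coords[j, ])^2)^b)
      q <- min(max(q, eps), 1 - eps)
      pij <- p[i, j]
      if (pij > 0) total <- total + pij * log(pij / q)
      if (pij < 1) total <- total + (1 - pij) * log((1 - pij) / (1 - q))
    }
  }
  total
}

# reference DBSCAN from the all-pairs distance matrix: core components via
# igraph, clusters ordered by their minimal core index, borders attached to
# the earliest-formed cluster with a core within eps
oracle_dbscan <- function(points, eps, min_samples) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(d)
  within <- d <= eps * (1 + 1e-12)
  core <- rowSums(within) >= min_samples       # self-inclusive (diag TRUE)
  labels <- rep(-1L, n)
  if (any(core)) {
    core_idx <- which(core)
    sub <- within[core_idx, core_idx, drop = FALSE]
    diag(sub) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(g)$membership
    # formation order = ascending minimal core index
    first_core <- tapply(core_idx, comp, min)
    order_map <- rank(first_core) - 1L
    labels[core_idx] <- as.integer(order_map[as.character(comp)])
    for (i in which(!core)) {
      reach <- core_idx[within[i, core_idx]]
      if (length(reach)) labels[i] <- min(labels[reach])
    }
  }
  labels
}

# pair-counting adjusted Rand index over all C(n,2) point pairs
oracle_ari <- function(lt, lp) {
  n <- length(lt)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- lt[i] == lt[j]
      sp <- lp[i] == lp[j]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  denom <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (denom == 0) return(1)
  2 * (a * d - b * c_) / denom
}

# NMI via the entropy route H(Y) + H(C) - H(Y, C)
oracle_nmi <- function(lt, lp) {
  n <- length(lt)
  ent <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  h_t <- ent(lt); h_p <- ent(lp)
  h_joint <- ent(paste(lt, lp))
  mi <- h_t + h_p - h_joint
  if (h_t + h_p == 0) return(1)
  if (mi <= 0) return(0)
  2 * mi / (h_t + h_p)
}

# per-point double-loop silhouette
oracle_silhouette <- function(points, labels) {
  keep <- labels != -1L
  points <- as.matrix(points)[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    di <- sqrt(colSums((t(points) - points[i, ])^2))
    a_i <- mean(di[own])
    b_i <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b_i <- min(b_i, mean(di[labels == cl]))
    }
    m <- max(a_i, b_i)
    s[i] <- if (m > 0) (b_i - a_i) / m else 0
  }
  mean(s)
}

# small uniform random spot field with random gene tags
random_field <- function(n, n_genes, dims = 2L, extent = 100, seed = 1L) {
  set.seed(seed)
  spot_table(matrix(runif(n * dims, 0, extent), ncol = dims),
             gene = sprintf("g%02d", sample.int(n_genes, n, replace = TRUE)))
}

# partitions agree up to label renaming: cross-table is a permutation matrix
same_partition <- function(a, b) {
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  a <- a[a != -1L]; b <- b[b != -1L]
  if (!length(a)) return(TRUE)
  ct <- table(a, b)
  all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L)
}
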