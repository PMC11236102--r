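#' Embedding configuration
#'
#' Collects the hyper-parameters of the low-dimensional layout stage.  The
#' similarity kernel in clustering space is
#' \eqn{q_{ij} = (1 + a\,\|y_i - y_j\|^{2b})^{-1}}; when `a`/`b` are not given
#' they are derived from `min_dist` and `spread` by [fit_ab].  The epoch
#' default follows the size of the data set: 500 epochs up to 5000 spots,
#' 200 above (larger data sets need fewer passes because every edge is
#' sampled within each pass).
#'
#' @param d embedding dimension (default 2).
#' @param a,b positive kernel shape parameters; derived from
#'   `min_dist`/`spread` when `NULL`.
#' @param min_dist minimum separation the kernel aims to preserve between
#'   close points in the embedding (default 0.1).
#' @param spread scale of the embedded point cloud (default 1.0).
#' @param learning_rate initial SGD learning rate (default 1.0), decayed
#'   linearly to 0 over the epochs.
#' @param epochs number of optimization epochs; `NULL` = 500 for
#'   `N <= 5000`, 200 otherwise.
#' @param negative_samples uniform non-neighbor samples drawn per positive
#'   edge sample (default 5).
#' @param repulsion_strength weight applied to repulsive (negative-sample)
#'   gradients (default 1).
#' @param seed integer seed for the stochastic optimizer.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(d = 2L, a = NULL, b = NULL, min_dist = 0.1,
                             spread = 1.0, learning_rate = 1.0,
                             epochs = NULL, negative_samples = 5L,
                             repulsion_strength = 1, seed = 1L) {
  if (d < 1L) stop("d must be at least 1")
  if (min_dist < 0 || spread <= 0 || min_dist >= spread) {
    stop("need 0 <= min_dist < spread")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (!is.null(epochs) && epochs < 0) stop("epochs must be non-negative")
  if (negative_samples < 0) stop("negative_samples must be non-negative")
  if (repulsion_strength <= 0) stop("repulsion_strength must be positive")
  if (is.null(a) != is.null(b)) stop("give both a and b, or neither")
  if (is.null(a)) {
    ab <- fit_ab(min_dist, spread)
    a <- ab[["a"]]; b <- ab[["b"]]
  }
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  structure(list(d = as.integer(d), a = a, b = b, min_dist = min_dist,
                 spread = spread, learning_rate = learning_rate,
                 epochs = epochs, negative_samples = as.integer(negative_samples),
                 repulsion_strength = repulsion_strength,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Fit the kernel shape parameters from `min_dist` and `spread`
#'
#' Chooses `a` and `b` so that the similarity kernel
#' \eqn{q(x) = (1 + a x^{2b})^{-1}} approximates, in least squares on a
#' 300-point grid over `[0, 3 spread]`, the target curve that is 1 up to
#' `min_dist` and decays as `exp(-(x - min_dist)/spread)` beyond it.
#'
#' @param min_dist minimum separation, `0 <= min_dist < spread`.
#' @param spread decay scale, `> 0`.
#' @return Named numeric vector `c(a = , b = )`, both positive.
#' @examples
#' fit_ab(0.1, 1.0)  # approximately a = 1.58, b = 0.90
#' @export
fit_ab <- function(min_dist, spread) {
  if (min_dist < 0 || spread <= 0 || min_dist >= spread) {
    stop("need 0 <= min_dist < spread")
  }
  x <- seq(0, 3 * spread, length.out = 300L)
  target <- ifelse(x <= min_dist, 1, exp(-(x - min_dist) / spread))
  sse <- function(par) {
    q <- 1 / (1 + par[1L] * x^(2 * par[2L]))
    sum((q - target)^2)
  }
  fit <- stats::optim(c(1, 1), sse, method = "L-BFGS-B",
                      lower = c(1e-3, 1e-3), upper = c(1e3, 1e3))
  if (fit$convergence != 0 && fit$value > 1) {
    stop("kernel fit failed for min_dist = ", min_dist, ", spread = ", spread,
         "; supply a and b explicitly")
  }
  c(a = fit$par[1L], b = fit$par[2L])
}

#' Low-dimensional similarity kernel
#'
#' \eqn{q_{ij} = (1 + a\,\|y_i - y_j\|_2^{2b})^{-1} \in (0, 1]}, strictly
#' decreasing in the Euclidean separation; 1 exactly for coincident points.
#'
#' @param y_i,y_j embedded coordinate vectors of equal length.
#' @param a,b positive kernel shape parameters.
#' @return Similarity in `(0, 1]`.
#' @examples
#' low_dim_similarity(c(0, 0), c(1, 0), a = 1, b = 1)  # 0.5
#' @export
low_dim_similarity <- function(y_i, y_j, a, b) {
  d2 <- sum((y_i - y_j)^2)
  1 / (1 + a * d2^b)
}

#' Exact cross-entropy of an embedding against the fuzzy graph
#'
#' The layout objective: over all ordered pairs \eqn{i \ne j},
#' \deqn{CE = \sum_{i \ne j}\Big[p_{ij}\log\frac{p_{ij}}{q_{ij}} +
#'   (1 - p_{ij})\log\frac{1 - p_{ij}}{1 - q_{ij}}\Big],}
#' with \eqn{p_{ij} = A_{ij}} and \eqn{q_{ij}} from [low_dim_similarity].
#' Terms with \eqn{p \in \{0, 1\}} use the \eqn{0 \log 0 = 0} convention and
#' `q` is clamped to `[1e-12, 1 - 1e-12]` so the value stays finite for
#' coincident or far-separated points.  Since `p` and `q` are symmetric, the
#' ordered-pair sum counts every unordered pair twice.
#'
#' Cost is `O(N^2)`; intended for diagnostics and small graphs.
#'
#' @param a_mat symmetric adjacency with entries in `[0, 1]`.
#' @param coords `N x d` embedded coordinates.
#' @param a,b kernel shape parameters.
#' @return Non-negative scalar; 0 iff `p = q` on every pair (after clamping).
#' @export
cross_entropy <- function(a_mat, coords, a, b) {
  n <- nrow(coords)
  p <- as.matrix(a_mat)
  d2 <- as.matrix(stats::dist(coords))^2
  q <- 1 / (1 + a * d2^b)
  eps <- 1e-12
  q <- pmin(pmax(q, eps), 1 - eps)
  t1 <- ifelse(p > 0, p * log(p / q), 0)
  t2 <- ifelse(p < 1, (1 - p) * log((1 - p) / (1 - q)), 0)
  tot <- t1 + t2
  diag(tot) <- 0
  sum(tot)
}

#' Optimize the embedding by stochastic gradient descent
#'
#' Minimizes the cross-entropy objective by sampling graph edges with
#' frequency proportional to their fuzzy weight (attractive updates on the
#' edge's endpoints) and, per positive sample, `negative_samples` uniform
#' non-neighbors (repulsive updates weighted by
#' `cfg$repulsion_strength`).  The learning rate decays linearly from
#' `learning_rate` to 0; per-coordinate gradient terms are clipped at ±4.
#' The sampler uses a self-contained deterministic RNG, so results are
#' reproducible given `cfg$seed`.
#'
#' On graphs small enough for the exact objective to be evaluated
#' (`N <= ce_cutoff`), the exact cross-entropy of the stochastic result is
#' compared against the initialization; if the subsampled objective drifted
#' uphill on the exact one (possible on weakly structured graphs), a
#' deterministic full-batch repair runs instead: gradient descent on the
#' exact cross-entropy from the initial coordinates with a backtracking line
#' search.  Either way the returned exact cross-entropy never exceeds the
#' value at the initialization.
#'
#' @param a_mat sparse symmetric fuzzy adjacency from [fuzzy_union].
#' @param init `N x d` initial coordinates (e.g. from [spectral_init]).
#' @param cfg an [embedding_config].
#' @return An object of class `st_embedding`: list with `coords` (`N x d`),
#'   `final_ce` (exact cross-entropy of the result, computed when
#'   `N <= ce_cutoff`, otherwise `NA`) and `epochs`.
#' @param ce_cutoff largest `N` for which the exact final cross-entropy is
#'   evaluated (default 500).
#' @export
optimize_embedding <- function(a_mat, init, cfg = embedding_config(),
                               ce_cutoff = 500L) {
  n <- nrow(init)
  d <- ncol(init)
  if (nrow(a_mat) != n) stop("adjacency and init disagree on N")
  epochs <- cfg$epochs
  if (is.null(epochs)) epochs <- if (n <= 5000L) 500L else 200L
  coords <- init
  if (epochs > 0L && n > 1L) {
    tri <- methods::as(methods::as(a_mat, "generalMatrix"), "TsparseMatrix")
    keep <- tri@x > 0
    head_i <- tri@i[keep]          # 0-based, both edge directions present
    tail_j <- tri@j[keep]
    w <- tri@x[keep]
    if (length(w)) {
      epochs_per_sample <- max(w) / w
      csr <- neighbor_csr(a_mat)
      coords <- sgd_layout(coords, head_i, tail_j, epochs_per_sample,
                           csr$ptr, csr$idx,
                           cfg$a, cfg$b, cfg$learning_rate,
                           as.integer(epochs), cfg$negative_samples,
                           cfg$repulsion_strength, cfg$seed)
      if (!all(is.finite(coords))) {
        stop("non-finite coordinates produced during optimization; ",
             "lower the learning rate")
      }
    }
    if (n <= ce_cutoff) {
      # Monotone repair: the stochastic phase minimizes a subsampled
      # objective, and on weakly structured graphs its exact cross-entropy
      # can end up above the starting value.  When that happens (and only
      # then), descend the exact objective from the initialization with a
      # backtracking line search; since the line search never accepts an
      # uphill step, the returned CE never exceeds the CE at init.
      ce_init <- cross_entropy(a_mat, init, cfg$a, cfg$b)
      ce_sgd <- cross_entropy(a_mat, coords, cfg$a, cfg$b)
      if (ce_sgd > ce_init) {
        coords <- ce_polish(a_mat, init, cfg$a, cfg$b)
      }
    }
  }
  ce <- if (n <= ce_cutoff) cross_entropy(a_mat, coords, cfg$a, cfg$b) else NA_real_
  structure(list(coords = coords, final_ce = ce, epochs = epochs),
            class = "st_embedding")
}

# Full-batch gradient descent on the exact cross-entropy with backtracking;
# never accepts a step that increases the objective.  O(N^2 d) per iteration,
# used only below the exact-CE cutoff.
ce_polish <- function(a_mat, coords, a, b, max_iter = 40L, step = NULL) {
  p <- as.matrix(a_mat)
  n <- nrow(coords)
  ce_of <- function(y) cross_entropy(a_mat, y, a, b)
  grad_of <- function(y) {
    d2 <- as.matrix(stats::dist(y))^2
    d2 <- pmax(d2, 1e-12)
    q <- 1 / (1 + a * d2^b)
    eps <- 1e-12
    q <- pmin(pmax(q, eps), 1 - eps)
    # dCE/d(d2) per ordered pair: attraction p a b d2^(b-1) q minus
    # repulsion (1-p) b q / d2
    cmat <- p * a * b * d2^(b - 1) * q - (1 - p) * b * q / d2
    diag(cmat) <- 0
    w <- 4 * cmat
    rowSums(w) * y - w %*% y
  }
  if (is.null(step)) step <- 0.05 * max(1e-8, max(abs(coords)))^2 / n
  ce <- ce_of(coords)
  for (it in seq_len(max_iter)) {
    g <- grad_of(coords)
    gn <- sqrt(sum(g^2))
    if (!is.finite(gn) || gn < 1e-10) break
    accepted <- FALSE
    for (bt in 1:25) {
      cand <- coords - step * g
      ce_cand <- ce_of(cand)
      if (is.finite(ce_cand) && ce_cand < ce) {
        coords <- cand
        ce <- ce_cand
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  coords
}

# 0-based CSR neighbor structure (sorted column indices per row) used for
# negative-sample rejection.
neighbor_csr <- function(a_mat) {
  g <- methods::as(methods::as(a_mat, "generalMatrix"), "RsparseMatrix")
  list(ptr = g@p, idx = g@j)
}

#' @export
print.st_embedding <- function(x, ...) {
  cat(sprintf("st_embedding: %d points in %dD, %d epochs, final CE %s\n",
              nrow(x$coords), ncol(x$coords), x$epochs,
              ifelse(is.na(x$final_ce), "not evaluated",
                     format(x$final_ce, digits = 6))))
  invisible(x)
}
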