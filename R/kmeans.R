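## K-means clustering of subjects in gene space: kmeans++ seeding in R,
## Lloyd iterations in compiled code, best of n_init restarts by total
## within-cluster sum of squares.

#' K-means clustering with kmeans++ restarts
#'
#' Lloyd iterations from kmeans++ initializations; the best of `n_init`
#' restarts by total within-cluster sum of squared Euclidean distances is
#' returned. Empty clusters are repaired by reseeding from the point
#' farthest from its assigned center. Deterministic given `seed`.
#'
#' @param x Numeric matrix, observations in rows (subjects x genes).
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param seed Optional integer seed.
#' @return A `kmeans_fit` list: `labels` (1..k, named by rownames),
#'   `centers` (k x p), `tot_withinss`, `sizes`, `n_iter`, `converged`.
#' @export
kmeans_cluster <- function(x, k, n_init = 10, max_iter = 300, seed = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_domain("x must be a finite numeric matrix")
  }
  k <- as.integer(k)
  if (k < 1L) stop_domain("k must be >= 1")
  if (k > nrow(x)) stop_domain("k exceeds the number of observations (", nrow(x), ")")
  run <- function() kmeans_restarts(x, k, n_init, max_iter)
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tr <- best$inertia_trace
  if (any(diff(tr) > 1e-8 * (abs(tr[-length(tr)]) + 1))) {
    stop("internal error: within-SS increased across Lloyd iterations")
  }
  labels <- best$labels + 1L
  names(labels) <- rownames(x)
  out <- list(labels = labels, centers = best$centers,
              tot_withinss = best$inertia_trace[best$n_iter],
              sizes = tabulate(labels, nbins = k),
              n_iter = best$n_iter, converged = best$converged)
  class(out) <- "kmeans_fit"
  out
}

#' Pooled within-cluster dispersion W_k
#'
#' `W_k = sum_r D_r / (2 n_r)` with `D_r` the sum of pairwise squared
#' Euclidean distances within cluster r; algebraically identical to the
#' total within-cluster sum of squared distances to centroids.
#'
#' @param x Observations x features matrix.
#' @param labels Cluster assignment (1..k), no empty clusters.
#' @param method `"centroid"` (default, fast) or `"pairwise"` (direct form,
#'   used as a numerical cross-check).
#' @return W_k (non-negative real).
#' @export
within_dispersion <- function(x, labels, method = c("centroid", "pairwise")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop_domain("labels must match rows of x")
  k <- max(labels)
  if (!all(seq_len(k) %in% labels)) stop_domain("empty cluster in labels")
  total <- 0
  for (r in seq_len(k)) {
    xr <- x[labels == r, , drop = FALSE]
    nr <- nrow(xr)
    if (method == "centroid") {
      ctr <- colMeans(xr)
      total <- total + sum(sweep(xr, 2, ctr, "-")^2)
    } else {
      dr <- sum(as.matrix(stats::dist(xr))^2)  # full symmetric matrix
      total <- total + dr / (2 * nr)
    }
  }
  total
}
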