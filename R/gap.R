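## Gap-statistic model selection for the number of sub-phenotypes:
## reference datasets uniform over each observed feature range, gap curve
## with 95% CIs, and the selection rule (maximal gap subject to CI overlap
## and a minimum cluster size).

#' Gap-statistic curve over k = 1..k_max
#'
#' For each k the observed data are clustered and `B` reference datasets
#' (uniform over each observed feature range) are clustered with the same
#' parameters. `gap_k = mean_b log W*_kb - log W_k`,
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`, and the 95% CI is
#' `gap_k +/- 1.96 s_k`. Computation is deterministic given `seed`, and
#' invariant to row order: rows are sorted by rowname before any random
#' draw and results are mapped back.
#'
#' @param x Subjects x genes matrix (rownames = subject IDs).
#' @param k_max Largest k (default 10).
#' @param B Number of reference datasets (default 50, >= 2).
#' @param n_init,max_iter Passed to [kmeans_cluster()].
#' @param seed Optional integer seed.
#' @return A `gap_curve` data frame with columns `k`, `log_Wk`,
#'   `expected_log_Wk_ref`, `gap`, `s`, `ci_low`, `ci_high`,
#'   `min_cluster_size`; the per-k clusterings of the observed data are
#'   attached as attribute `"clusterings"` and `B` as `"B"`.
#' @export
gap_statistic <- function(x, k_max = 10, B = 50, n_init = 10, max_iter = 300,
                          seed = NULL) {
  x <- as.matrix(x)
  if (B < 2) stop_domain("B must be >= 2")
  if (k_max < 1) stop_domain("k_max must be >= 1")
  if (k_max > nrow(x)) stop_domain("k_max exceeds the number of subjects")
  ord <- if (!is.null(rownames(x))) order(rownames(x)) else seq_len(nrow(x))
  xs <- x[ord, , drop = FALSE]
  n <- nrow(xs)

  compute <- function() {
    rng_lo <- apply(xs, 2, min)
    rng_hi <- apply(xs, 2, max)
    keep <- rng_hi > rng_lo
    if (!all(keep)) {
      warning(sum(!keep), " zero-range feature(s) dropped from reference generation")
    }
    lo <- rng_lo[keep]; hi <- rng_hi[keep]
    p_ref <- sum(keep)

    fits <- vector("list", k_max)
    log_w <- min_size <- numeric(k_max)
    for (k in seq_len(k_max)) {
      fits[[k]] <- kmeans_cluster(xs, k, n_init = n_init, max_iter = max_iter)
      log_w[k] <- log(fits[[k]]$tot_withinss)
      min_size[k] <- min(fits[[k]]$sizes)
    }
    log_w_ref <- matrix(0, B, k_max)
    for (b in seq_len(B)) {
      ref <- matrix(runif(n * p_ref, rep(lo, each = n), rep(hi, each = n)),
                    nrow = n, ncol = p_ref)
      for (k in seq_len(k_max)) {
        log_w_ref[b, k] <- log(kmeans_cluster(ref, k, n_init = n_init,
                                              max_iter = max_iter)$tot_withinss)
      }
    }
    list(fits = fits, log_w = log_w, min_size = min_size, log_w_ref = log_w_ref)
  }
  res <- if (is.null(seed)) compute() else withr::with_seed(seed, compute())

  gap <- colMeans(res$log_w_ref) - res$log_w
  s <- apply(res$log_w_ref, 2, sd) * sqrt(1 + 1 / B)
  curve <- data.frame(
    k = seq_len(k_max), log_Wk = res$log_w,
    expected_log_Wk_ref = colMeans(res$log_w_ref),
    gap = gap, s = s,
    ci_low = gap - 1.96 * s, ci_high = gap + 1.96 * s,
    min_cluster_size = res$min_size)
  # map clusterings back to input row order
  inv <- order(ord)
  clusterings <- lapply(res$fits, function(f) f$labels[inv])
  attr(curve, "clusterings") <- clusterings
  attr(curve, "B") <- B
  class(curve) <- c("gap_curve", "data.frame")
  curve
}

#' Select the number of clusters from a gap curve
#'
#' Candidates are the k whose 95% CI overlaps the CI of the globally
#' maximal gap ("similar performance"). Among candidates whose clustering
#' keeps every cluster above the minimum size, the selected k is the
#' smallest one whose gap lies within `se_factor * s` of the best
#' admissible gap; gaps closer than that are statistically
#' indistinguishable at the curve's own Monte-Carlo resolution, and ties
#' resolve toward smaller k (parsimony). With `se_factor = 0` this is a
#' strict arg-max.
#'
#' @param curve A [gap_statistic()] result (or a data frame with columns
#'   `k`, `gap`, `s`, `ci_low`, `ci_high`, `min_cluster_size`).
#' @param min_cluster_size Minimum admissible cluster size; the default 11
#'   encodes "more than 10 subjects per cluster".
#' @param se_factor Width of the tie band in units of `s` (default 1).
#' @return A `k_selection` list: `k` (selected), `audit` (candidate set,
#'   size eliminations, gap arg-max, tie band).
#' @export
select_k <- function(curve, min_cluster_size = 11, se_factor = 1) {
  need <- c("k", "gap", "s", "ci_low", "ci_high", "min_cluster_size")
  if (!all(need %in% names(curve))) {
    stop_domain("curve must contain columns: ", paste(need, collapse = ", "))
  }
  g <- which.max(curve$gap)
  overlap <- curve$ci_high >= curve$ci_low[g] & curve$ci_low <= curve$ci_high[g]
  size_ok <- curve$min_cluster_size >= min_cluster_size
  admissible <- which(overlap & size_ok)
  if (!length(admissible)) {
    stop_domain("no admissible k: every candidate with similar performance ",
                "has a cluster of fewer than ", min_cluster_size, " subjects")
  }
  m <- admissible[which.max(curve$gap[admissible])]
  band <- curve$gap[m] - se_factor * curve$s[m]
  chosen <- admissible[curve$gap[admissible] >= band][1]
  out <- list(
    k = curve$k[chosen],
    audit = list(
      global_max_k = curve$k[g],
      candidates_ci_overlap = curve$k[overlap],
      eliminated_by_size = curve$k[overlap & !size_ok],
      admissible = curve$k[admissible],
      best_admissible_k = curve$k[m],
      tie_band = c(lower = band, best_gap = curve$gap[m]),
      min_cluster_size = min_cluster_size,
      se_factor = se_factor))
  class(out) <- "k_selection"
  out
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Selected k =", x$k, "\n")
  cat("  global gap maximum at k =", x$audit$global_max_k, "\n")
  cat("  CI-overlap candidates:", paste(x$audit$candidates_ci_overlap, collapse = ", "), "\n")
  if (length(x$audit$eliminated_by_size)) {
    cat("  eliminated (cluster <", x$audit$min_cluster_size, "subjects):",
        paste(x$audit$eliminated_by_size, collapse = ", "), "\n")
  }
  invisible(x)
}

#' PCA projection of subjects
#'
#' Centered singular-value projection of subjects into the leading
#' principal components, with the fraction of total variance explained by
#' each component.
#'
#' @param expression Genes x samples matrix (subjects are projected).
#' @param n_components Number of components (default 2).
#' @return List with `coords` (samples x n_components) and
#'   `var_explained` (fractions, non-increasing, summing to <= 1).
#' @export
pca_project <- function(expression, n_components = 2) {
  x <- t(as.matrix(expression))
  if (n_components > min(dim(x))) {
    stop_domain("n_components exceeds min(n_subjects, n_genes)")
  }
  if (all(apply(x, 2, function(v) max(v) == min(v)))) {
    stop_domain("constant matrix has zero variance; PCA undefined")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(n_components), drop = FALSE],
       var_explained = frac[seq_len(n_components)])
}
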