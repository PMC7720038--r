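## Subtype gene signatures: quantile normalization, expression filtering,
## one-vs-rest differential expression (Welch t on log2-scale values) and
## the fold-change / FDR gene gates.

#' Quantile normalization
#'
#' Forces every sample (column) to the same empirical distribution: the
#' mean of the sorted columns. Rank ties within a column receive the mean
#' of the tied quantile targets. Idempotent.
#'
#' @param x Genes x samples matrix, no missing values.
#' @return Normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_domain("quantile normalization requires complete data")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Filter genes by expression level
#'
#' Keeps genes with at least `min_samples` samples at or above
#' `min_value`.
#'
#' @param x Genes x samples matrix.
#' @param min_value Expression threshold (default 10).
#' @param min_samples Minimum number of samples meeting it (default 10).
#' @return Character vector of retained gene IDs (rownames), or row
#'   indices if unnamed.
#' @export
filter_expressed <- function(x, min_value = 10, min_samples = 10) {
  if (min_value < 0 || min_samples < 0) stop_domain("thresholds must be >= 0")
  keep <- rowSums(x >= min_value) >= min_samples
  if (is.null(rownames(x))) which(keep) else rownames(x)[keep]
}

#' One-vs-rest differential expression
#'
#' Per gene, a Welch two-sample t test of the subtype against all other
#' subjects on the (log2-scale) expression values; `log2_fc` is the mean
#' difference (subtype minus rest) and q-values are Benjamini-Hochberg
#' adjusted across the supplied genes.
#'
#' @param x Genes x samples matrix (typically already restricted to
#'   [filter_expressed()] genes).
#' @param labels Named subtype assignment covering every sample.
#' @param subtype The subtype to contrast against the rest.
#' @return Data frame: `gene_id`, `log2_fc`, `statistic`, `df`,
#'   `p_value`, `q_value`.
#' @export
de_one_vs_rest <- function(x, labels, subtype) {
  x <- as.matrix(x)
  lab <- labels[match(colnames(x), names(labels))]
  if (anyNA(lab)) stop_domain("labels missing for some samples")
  g1 <- lab == subtype
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop_domain("both groups need at least 2 samples")
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, !g1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  tstat[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign((m1 - m2)[zero]))
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  df[zero] <- NA_real_
  data.frame(gene_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             log2_fc = unname(m1 - m2), statistic = unname(tstat),
             df = unname(df), p_value = unname(p),
             q_value = bh_adjust(unname(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change / FDR gene gates
#'
#' Twofold (by default) up- and downregulated genes at q below the FDR
#' threshold. Fold-change boundaries are inclusive
#' (`|log2_fc| >= log2(fc_threshold)`); the q gate is strict.
#'
#' @param results A [de_one_vs_rest()] data frame.
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2).
#' @param q_threshold FDR threshold (default 0.1).
#' @return List with character vectors `up` and `down` (disjoint).
#' @export
select_degs <- function(results, fc_threshold = 2, q_threshold = 0.1) {
  lfc <- log2(fc_threshold)
  sig <- results$q_value < q_threshold
  list(up = results$gene_id[sig & results$log2_fc >= lfc],
       down = results$gene_id[sig & results$log2_fc <= -lfc])
}
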