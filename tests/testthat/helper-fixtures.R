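# shared fixtures and independent oracles

# small, fast cohort for structural tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_subjects = 60, n_genes = 300, n_informative = 60,
         effect_size = 2, subtype_proportions = c(20, 20, 20) / 60,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# brute-force Freeman-Halton p-value for 2 x c tables by complete
# enumeration of tables with the observed margins
fisher_p_bruteforce <- function(tab) {
  stopifnot(nrow(tab) == 2)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  log_p_table <- function(top) {
    sum(lchoose(cs, top)) - lchoose(n, rs[1])
  }
  p_obs <- log_p_table(tab[1, ])
  tops <- expand.grid(lapply(cs, function(cj) 0:cj))
  tops <- tops[rowSums(tops) == rs[1], , drop = FALSE]
  total <- 0
  for (i in seq_len(nrow(tops))) {
    lp <- log_p_table(as.numeric(tops[i, ]))
    if (exp(lp) <= exp(p_obs) * (1 + 1e-7)) total <- total + exp(lp)
  }
  total
}

# exhaustive minimum within-SS over all 2-partitions of the rows of x
best_two_partition_ss <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    ss <- function(m) {
      xm <- x[m, , drop = FALSE]
      sum(sweep(xm, 2, colMeans(xm), "-")^2)
    }
    w <- ss(g) + ss(!g)
    if (w < best) best <- w
  }
  best
}

# adjusted Rand index (via mclust when available)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# mean silhouette width for small 2-D configurations
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(tapply(d[i, !own], labels[!own], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
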