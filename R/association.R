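## Subtype-vs-clinical characterization statistics: exact tests for
## categorical variables, rank tests and effect sizes for continuous
## variables, multiplicity adjustment, and a Table-1-style summary.

#' Freeman-Halton Fisher exact test for r x c tables
#'
#' Exact test of independence in an r x c contingency table: the p-value
#' sums the multivariate-hypergeometric probabilities, over all tables
#' with the observed margins, of tables no more probable than the observed
#' one (with a small relative tolerance absorbing floating-point ties).
#'
#' @param counts r x c matrix of non-negative integer counts, at least
#'   2 x 2, with positive margins.
#' @return A `test_result` list: `statistic` (probability of the observed
#'   table), `p_value`, `df` (NA; the test is exact).
#' @examples
#' # deaths/survivors across three subtypes
#' fisher_exact_rxc(matrix(c(10, 21, 7, 22, 3, 33), nrow = 2))
#' @export
fisher_exact_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop_domain("contingency table must be at least 2 x 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_domain("degenerate table: zero margin")
  }
  ft <- fisher.test(counts, workspace = 2e7)
  # multivariate hypergeometric probability of the observed table
  logp <- sum(lgamma(rowSums(counts) + 1)) + sum(lgamma(colSums(counts) + 1)) -
    lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  structure(list(statistic = exp(logp), p_value = ft$p.value,
                 df = NA_integer_, effect_size = NA_real_),
            class = "test_result")
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction, compared to a chi-square distribution
#' with k - 1 degrees of freedom. When every value is identical H = 0 and
#' p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return A `test_result` list: `statistic` (H), `p_value`, `df`,
#'   `effect_size` (rank-based eta squared, see [eta_squared()]).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop_domain("need at least 2 non-empty groups")
  if (length(values) != length(groups)) stop_domain("values and groups must align")
  if (length(unique(values)) == 1L) {
    out <- list(statistic = 0, p_value = 1,
                df = nlevels(droplevels(groups)) - 1L,
                effect_size = 0)
    class(out) <- "test_result"
    return(out)
  }
  kt <- kruskal.test(values, groups)
  h <- unname(kt$statistic)
  k <- nlevels(droplevels(groups)); n <- length(values)
  eta2 <- if (n > k) max(0, min(1, (h - k + 1) / (n - k))) else NA_real_
  out <- list(statistic = h, p_value = kt$p.value,
              df = unname(kt$parameter),
              effect_size = eta2)
  class(out) <- "test_result"
  out
}

#' Eta-squared effect size for group comparisons
#'
#' Rank-based estimator consistent with the Kruskal-Wallis framework:
#' `eta2_H = (H - k + 1) / (n - k)`, floored at 0. The ANOVA-based
#' estimator (between-group over total sum of squares) is available via
#' `method = "anova"`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, n > k).
#' @param method `"rank"` (default) or `"anova"`.
#' @return Effect size in `[0, 1]`.
#' @export
eta_squared <- function(values, groups, method = c("rank", "anova")) {
  method <- match.arg(method)
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop_domain("need at least 2 groups")
  if (n <= k) stop_domain("eta squared requires n > k")
  if (method == "rank") {
    if (length(unique(values)) == 1L) return(0)
    h <- unname(kruskal.test(values, groups)$statistic)
    max(0, min(1, (h - k + 1) / (n - k)))
  } else {
    gm <- mean(values)
    ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
    sst <- sum((values - gm)^2)
    if (sst == 0) return(0)
    ssb / sst
  }
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values (same order as input).
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

summary_continuous <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  sprintf("%.4g [%.4g, %.4g]", q[1], q[2], q[3])
}

#' Table-1-style characterization of subtypes
#'
#' Continuous variables are summarized as median \[IQR\] per subtype with a
#' Kruskal-Wallis p-value; categorical variables as n (%) with a
#' Freeman-Halton Fisher exact p-value. Per-subject outcome rows
#' (ventilator days, VFD, PICU mortality) are included when `events` is
#' supplied. P-values are reported unadjusted.
#'
#' @param clinical Validated clinical table.
#' @param labels Named subtype assignment (1..k), one per subject.
#' @param events Optional validated events table.
#' @return Data frame: `variable`, `type`, one summary column per subtype,
#'   `p_value`, `test`.
#' @export
characterize_subtypes <- function(clinical, labels, events = NULL) {
  clinical <- validate_clinical(clinical)
  lab <- labels[match(clinical$subject_id, names(labels))]
  if (anyNA(lab)) stop_domain("labels missing for some subjects in clinical table")
  lab <- factor(as.integer(lab))
  k <- nlevels(lab)
  sub_cols <- paste0("subtype_", levels(lab))

  clinical$vasopressor_score <- vasopressor_score(
    clinical$dopamine, clinical$dobutamine, clinical$epinephrine,
    clinical$norepinephrine, clinical$phenylephrine, clinical$milrinone,
    clinical$vasopressin)

  cont_vars <- c("age", "prism_iii", "nonpulm_organ_failures",
                 "vasopressor_score", "anc", "alc",
                 "pf_onset", "oi_onset", "pf_24h", "oi_24h")
  cat_vars <- c(sex = "female", immunocompromised = NA, stem_cell_transplant = NA,
                etiology_direct = NA, etiology_infectious = NA)

  if (!is.null(events)) {
    es <- events_summary(events)
    m <- match(clinical$subject_id, es$subject_id)
    clinical$vent_days <- es$vent_days[m]
    clinical$vfd <- es$vfd[m]
    clinical$picu_mortality <- !es$picu_survivor[m]
    cont_vars <- c(cont_vars, "vent_days", "vfd")
    cat_vars <- c(cat_vars, picu_mortality = NA)
  }

  rows <- list()
  for (v in cont_vars) {
    vals <- clinical[[v]]
    summ <- tapply(vals, lab, summary_continuous)
    p <- tryCatch(kruskal_wallis(vals, lab)$p_value, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- c(
      list(variable = v, type = "continuous"),
      setNames(as.list(unname(summ)), sub_cols),
      list(p_value = p, test = "kruskal-wallis"))
  }
  for (v in names(cat_vars)) {
    raw <- clinical[[v]]
    flag <- if (!is.na(cat_vars[[v]])) raw == cat_vars[[v]] else as.logical(raw)
    tab <- rbind(yes = tapply(flag, lab, sum), no = tapply(!flag, lab, sum))
    pct <- round(100 * tab["yes", ] / colSums(tab))
    summ <- sprintf("%d (%d%%)", tab["yes", ], pct)
    p <- if (any(rowSums(tab) == 0)) NA_real_ else fisher_exact_rxc(tab)$p_value
    rows[[length(rows) + 1L]] <- c(
      list(variable = v, type = "categorical"),
      setNames(as.list(summ), sub_cols),
      list(p_value = p, test = "fisher-exact"))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
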