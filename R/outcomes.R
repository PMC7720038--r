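## Subtype-outcome inference: logistic regression for PICU mortality,
## Fine-Gray subdistribution-hazard regression for sustained extubation
## with death as the competing risk, Kaplan-Meier curves, log-rank tests
## and Aalen-Johansen cumulative incidence.

tidy_fit <- function(terms, beta, se, conf_level, exp_label) {
  z <- beta / se
  q <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = terms, estimate = beta, se = se,
             ratio = exp(beta),
             ci_low = exp(beta - q * se), ci_high = exp(beta + q * se),
             p_value = 2 * pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

as_design <- function(covariates) {
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  mm <- model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]  # drop intercept; models add their own
}

#' Logistic regression with Wald inference
#'
#' Maximum likelihood via iteratively reweighted least squares, with odds
#' ratios, Wald 95% CIs and p-values. Perfect separation and
#' rank-deficient designs raise explicit errors.
#'
#' @param y Binary response (0/1 or logical).
#' @param covariates Data frame or matrix of covariates (an intercept is
#'   added; factors are expanded to indicators).
#' @param conf_level Confidence level (default 0.95).
#' @return A `logistic_fit` list: `coefficients` data frame (term,
#'   estimate, se, ratio = OR, ci_low, ci_high, p_value), `converged`,
#'   `n_iter`, `n`.
#' @export
fit_logistic <- function(y, covariates, conf_level = 0.95) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_domain("y must be binary (0/1)")
  x <- as_design(covariates)
  if (nrow(x) != length(y)) stop_domain("covariates must match length of y")
  full <- cbind(1, x)
  if (qr(full)$rank < ncol(full)) stop_domain("design matrix is rank deficient")
  df <- data.frame(.y = y, x, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (fit$deviance < 1e-7 || (sep_warn && max(abs(coef(fit))) > 15)) {
    stop_domain("perfect separation detected; logistic estimates do not exist")
  }
  if (!fit$converged) stop_domain("logistic regression did not converge")
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- list(coefficients = tidy_fit(names(beta), unname(beta), unname(se),
                                      conf_level, "OR"),
              converged = fit$converged, n_iter = fit$iter, n = length(y))
  class(out) <- "logistic_fit"
  out
}

#' Fine-Gray subdistribution-hazard regression
#'
#' Fits the Fine-Gray model for the subdistribution hazard of the event of
#' interest, keeping subjects with prior competing events in later risk
#' sets with inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimate of the censoring distribution (Breslow handling
#' of ties). Reported standard errors are the model's robust (sandwich)
#' estimates.
#'
#' @param time Event/censoring times, > 0.
#' @param event Integer status: 0 = censored, 1 = event of interest
#'   (extubated alive), 2 = competing event (death).
#' @param covariates Data frame or matrix of covariates.
#' @param event_of_interest Failure code modeled (default 1).
#' @param conf_level Confidence level (default 0.95).
#' @return A `fine_gray_fit` list: `coefficients` data frame (term,
#'   estimate, se, ratio = SHR, ci_low, ci_high, p_value), `converged`,
#'   `n`, `n_events`.
#' @export
fit_fine_gray <- function(time, event, covariates, event_of_interest = 1,
                          conf_level = 0.95) {
  if (any(time <= 0)) stop_domain("times must be positive")
  if (!all(event %in% c(0, 1, 2))) stop_domain("event must be coded 0/1/2")
  if (!any(event == event_of_interest)) {
    stop_domain("no events of interest (code ", event_of_interest, ") observed")
  }
  x <- as_design(covariates)
  if (nrow(x) != length(time)) stop_domain("covariates must match length of time")
  fit <- cmprsk::crr(ftime = time, fstatus = event, cov1 = x,
                     failcode = event_of_interest, cencode = 0,
                     gtol = 1e-7, maxiter = 100)
  if (!fit$converged) stop_domain("Fine-Gray regression did not converge")
  beta <- fit$coef
  se <- sqrt(diag(fit$var))
  out <- list(coefficients = tidy_fit(colnames(x), unname(beta), unname(se),
                                      conf_level, "SHR"),
              converged = fit$converged, n = length(time),
              n_events = sum(event == event_of_interest))
  class(out) <- "fine_gray_fit"
  out
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Standard partial-likelihood fit; exposed both as a utility and as the
#' reduction oracle for [fit_fine_gray()] (the two coincide when there are
#' no competing events).
#'
#' @param time Event/censoring times, > 0.
#' @param event Binary status (1 = event).
#' @param covariates Data frame or matrix of covariates.
#' @param conf_level Confidence level (default 0.95).
#' @return A `cox_fit` list with a `coefficients` data frame as in
#'   [fit_fine_gray()] (ratio = HR).
#' @export
fit_cox <- function(time, event, covariates, conf_level = 0.95) {
  if (any(time <= 0)) stop_domain("times must be positive")
  x <- as_design(covariates)
  df <- data.frame(.t = time, .e = as.numeric(event), x, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(.t, .e) ~",
                                 paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-10, toler.chol = 1e-12,
                                                           iter.max = 100))
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- list(coefficients = tidy_fit(colnames(x), unname(beta), unname(se),
                                      conf_level, "HR"),
              converged = TRUE, n = length(time), n_events = sum(event == 1))
  class(out) <- "cox_fit"
  out
}

#' Kaplan-Meier survival estimate
#'
#' @param time Event/censoring times, > 0.
#' @param event_observed Binary indicator (1 = event).
#' @return Data frame `(time, survival)` defining a right-continuous step
#'   function with S(0) = 1.
#' @export
km_estimate <- function(time, event_observed) {
  if (any(time <= 0)) stop_domain("times must be positive")
  sf <- survival::survfit(survival::Surv(time, as.numeric(event_observed)) ~ 1)
  data.frame(time = c(0, sf$time), survival = c(1, sf$surv))
}

#' Log-rank test (with optional pairwise comparisons)
#'
#' Chi-square statistic with g - 1 degrees of freedom from
#' observed-minus-expected event sums; `pairwise = TRUE` additionally runs
#' every two-group comparison, unadjusted.
#'
#' @param time Event/censoring times, > 0.
#' @param event_observed Binary indicator (1 = event).
#' @param groups Group labels (>= 2 non-empty groups).
#' @param pairwise Also run all pairwise tests (default FALSE).
#' @return A `test_result` list (`statistic`, `p_value`, `df`), with a
#'   `pairwise` data frame element when requested.
#' @export
logrank_test <- function(time, event_observed, groups, pairwise = FALSE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop_domain("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop_domain("empty group")
  sd1 <- survival::survdiff(
    survival::Surv(time, as.numeric(event_observed)) ~ groups, rho = 0)
  df <- nlevels(groups) - 1L
  out <- list(statistic = unname(sd1$chisq),
              p_value = pchisq(sd1$chisq, df, lower.tail = FALSE),
              df = df, effect_size = NA_real_)
  if (pairwise) {
    lv <- levels(groups)
    prs <- utils::combn(lv, 2, simplify = FALSE)
    out$pairwise <- do.call(rbind, lapply(prs, function(pr) {
      sel <- groups %in% pr
      sd2 <- survival::survdiff(
        survival::Surv(time[sel], as.numeric(event_observed)[sel]) ~
          droplevels(groups[sel]), rho = 0)
      data.frame(group1 = pr[1], group2 = pr[2],
                 statistic = unname(sd2$chisq),
                 p_value = pchisq(sd2$chisq, 1, lower.tail = FALSE))
    }))
  }
  class(out) <- "test_result"
  out
}

#' Aalen-Johansen cumulative incidence functions
#'
#' Nonparametric per-cause cumulative incidence under competing risks. At
#' every time the cause-specific incidences plus overall survival sum to 1.
#'
#' @param time Event/censoring times, > 0.
#' @param event Integer status: 0 = censored, other codes = causes.
#' @return A named list, one data frame `(time, incidence)` per cause,
#'   with attribute `"overall_survival"` (the all-cause Kaplan-Meier).
#' @export
cumulative_incidence <- function(time, event) {
  if (any(time <= 0)) stop_domain("times must be positive")
  causes <- sort(unique(event[event != 0]))
  if (!length(causes)) {
    km <- km_estimate(time, rep(0, length(time)))
    out <- list()
    attr(out, "overall_survival") <- km
    return(out)
  }
  ci <- cmprsk::cuminc(ftime = time, fstatus = event, cencode = 0)
  out <- list()
  for (cs in causes) {
    el <- ci[[paste("1", cs)]]
    out[[as.character(cs)]] <- data.frame(time = el$time, incidence = el$est)
  }
  attr(out, "overall_survival") <- km_estimate(time, as.numeric(event != 0))
  out
}

#' Evaluate a step function at given times
#'
#' Right-continuous evaluation of the `(time, value)` step functions
#' returned by [km_estimate()] and [cumulative_incidence()].
#'
#' @param step Data frame whose first column is time and second the value.
#' @param at Times at which to evaluate.
#' @param v0 Value before the first time point (1 for survival, 0 for
#'   incidence).
#' @return Numeric vector.
#' @export
step_at <- function(step, at, v0 = NULL) {
  if (is.null(v0)) v0 <- step[[2]][1]
  step_eval(step[[1]], step[[2]], at, v0)
}

#' Subtype-outcome models across adjustment presets
#'
#' Fits the mortality logistic model and the extubation Fine-Gray model
#' for subtype contrasts (reference = subtype 1) under the named
#' adjustment sets: none, PRISM III, immunocompromised, both, and both
#' plus ANC or ALC.
#'
#' @param clinical Validated clinical table.
#' @param labels Named subtype assignment.
#' @param events Validated events table.
#' @param adjust Character vector of preset names (see Details); default
#'   all six.
#' @return Data frame with one row per contrast x preset x model:
#'   `adjustment`, `model`, `term`, `estimate`, `ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `note`.
#' @export
fit_outcome_models <- function(clinical, labels, events,
                               adjust = names(adjustment_presets())) {
  presets <- adjustment_presets()
  bad <- setdiff(adjust, names(presets))
  if (length(bad)) stop_domain("unknown adjustment preset(s): ", paste(bad, collapse = ", "))
  clinical <- validate_clinical(clinical)
  es <- events_summary(events)
  m <- match(clinical$subject_id, es$subject_id)
  if (anyNA(m)) stop_domain("events missing for some subjects")
  lab <- labels[match(clinical$subject_id, names(labels))]
  if (anyNA(lab)) stop_domain("labels missing for some subjects")
  subtype <- factor(paste0("subtype", as.integer(lab)))
  y_death <- as.numeric(!es$picu_survivor[m])

  rows <- list()
  for (a in adjust) {
    cov <- data.frame(subtype = subtype)
    for (v in presets[[a]]) cov[[v]] <- clinical[[v]]
    lg <- tryCatch(fit_logistic(y_death, cov), error = function(e) e)
    fg <- tryCatch(fit_fine_gray(es$time[m], es$event[m], cov,
                                 event_of_interest = 1),
                   error = function(e) e)
    for (res in list(list(fit = lg, model = "mortality_logistic"),
                     list(fit = fg, model = "extubation_fine_gray"))) {
      if (inherits(res$fit, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          adjustment = a, model = res$model, term = NA_character_,
          estimate = NA_real_, ratio = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p_value = NA_real_,
          note = conditionMessage(res$fit), stringsAsFactors = FALSE)
      } else {
        cf <- res$fit$coefficients
        cf <- cf[grepl("^subtype", cf$term), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          adjustment = a, model = res$model, term = cf$term,
          estimate = cf$estimate, ratio = cf$ratio, ci_low = cf$ci_low,
          ci_high = cf$ci_high, p_value = cf$p_value, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Named covariate-adjustment presets for the outcome models
#' @return Named list of clinical column sets.
#' @export
adjustment_presets <- function() {
  list(unadjusted = character(0),
       prism = "prism_iii",
       immunocompromised = "immunocompromised",
       prism_immunocompromised = c("prism_iii", "immunocompromised"),
       prism_immunocompromised_anc = c("prism_iii", "immunocompromised", "anc"),
       prism_immunocompromised_alc = c("prism_iii", "immunocompromised", "alc"))
}
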