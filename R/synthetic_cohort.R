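## Synthetic cohort generator: planted expression subtypes, subtype-linked
## clinical covariates, and competing-risk ventilation outcomes. The
## defaults emulate a 96-subject pediatric ARDS cohort with three latent
## subtypes of sizes 31/29/36, subtype-linked immunocompromise prevalence
## (32/48/14%) and 28-day mortality (32/24/8%).

#' Simulation configuration
#'
#' @param n_subjects Number of subjects.
#' @param n_genes Number of genes.
#' @param k_true Number of latent subtypes (>= 1).
#' @param n_informative Number of informative genes (split into disjoint
#'   per-subtype blocks); must not exceed `n_genes`.
#' @param effect_size Mean log2 shift per informative gene in its subtype.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param subtype_proportions Simplex vector of length `k_true`; subjects
#'   are apportioned deterministically by largest remainder.
#' @param immunocompromised_prev Per-subtype immunocompromise probability.
#' @param death_prob_28d Per-subtype probability of death by day 28.
#' @param extubation_rate Baseline daily rate of the extubation-time law.
#' @param reintubation_prob Probability that an extubated survivor has a
#'   late (> 24 h) reintubation episode adding ventilator days.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_subjects = 96, n_genes = 2000, k_true = 3,
                              n_informative = 200, effect_size = 2,
                              noise_sd = 1,
                              subtype_proportions = c(31, 29, 36) / 96,
                              immunocompromised_prev = c(0.32, 0.48, 0.14),
                              death_prob_28d = c(0.32, 0.24, 0.08),
                              extubation_rate = 0.1,
                              reintubation_prob = 0.1,
                              seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
              k_true = as.integer(k_true), n_informative = as.integer(n_informative),
              effect_size = effect_size, noise_sd = noise_sd,
              subtype_proportions = subtype_proportions,
              immunocompromised_prev = recycle_k(immunocompromised_prev, k_true),
              death_prob_28d = recycle_k(death_prob_28d, k_true),
              extubation_rate = extubation_rate,
              reintubation_prob = reintubation_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

recycle_k <- function(x, k) {
  if (length(x) == 1L) rep(x, k) else x
}

validate_config <- function(cfg) {
  if (cfg$n_subjects < 1) stop_domain("invalid config: n_subjects must be >= 1")
  if (cfg$n_genes < 1) stop_domain("invalid config: n_genes must be >= 1")
  if (cfg$k_true < 1) stop_domain("invalid config: k_true must be >= 1")
  if (cfg$n_informative > cfg$n_genes) {
    stop_domain("invalid config: n_informative exceeds n_genes")
  }
  if (cfg$n_informative < 0) stop_domain("invalid config: n_informative must be >= 0")
  if (cfg$effect_size < 0) stop_domain("invalid config: effect_size must be >= 0")
  if (cfg$noise_sd <= 0) stop_domain("invalid config: noise_sd must be positive")
  if (length(cfg$subtype_proportions) != cfg$k_true) {
    stop_domain("invalid config: subtype_proportions must have length k_true")
  }
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9) {
    stop_domain("invalid config: subtype_proportions must sum to 1")
  }
  if (any(cfg$subtype_proportions < 0)) {
    stop_domain("invalid config: subtype_proportions must be non-negative")
  }
  for (f in c("immunocompromised_prev", "death_prob_28d")) {
    if (length(cfg[[f]]) != cfg$k_true) {
      stop_domain("invalid config: ", f, " must have length k_true")
    }
    check_prob(cfg[[f]], paste0("invalid config: ", f))
  }
  if (cfg$extubation_rate <= 0) stop_domain("invalid config: extubation_rate must be positive")
  check_prob(cfg$reintubation_prob, "invalid config: reintubation_prob")
  if (cfg$seed >= .Machine$integer.max - 10L) stop_domain("invalid config: seed too large")
  cfg
}

subject_ids <- function(n) sprintf("S%03d", seq_len(n))

# deterministic subtype labels by largest-remainder apportionment
true_labels_for <- function(cfg) {
  sizes <- largest_remainder(cfg$n_subjects, cfg$subtype_proportions)
  setNames(rep(seq_len(cfg$k_true), sizes), subject_ids(cfg$n_subjects))
}

#' Generate a planted-subtype expression matrix
#'
#' Gene baselines are drawn uniformly on the log2-like range 6-12 (the
#' scale of summarized microarray output). The first `n_informative` genes
#' are split into `k_true` disjoint blocks; each subtype's block mean is
#' shifted by `+effect_size`. Remaining genes are exchangeable across
#' subtypes. Values are truncated at 0.
#'
#' @param config A [simulation_config()].
#' @return List with `expression` (genes x samples matrix) and
#'   `true_labels` (named subtype index per subject).
#' @export
generate_expression <- function(config) {
  config <- validate_config(config)
  labels <- true_labels_for(config)
  n <- config$n_subjects; p <- config$n_genes; k <- config$k_true
  withr::with_seed(sub_seed(config$seed, "expression"), {
    mu <- runif(p, 6, 12)
    x <- matrix(rnorm(p * n, sd = config$noise_sd), nrow = p, ncol = n) + mu
    if (config$n_informative > 0 && config$effect_size > 0) {
      block_sizes <- largest_remainder(config$n_informative, rep(1 / k, k))
      stops <- cumsum(block_sizes)
      starts <- stops - block_sizes + 1L
      for (j in seq_len(k)) {
        if (block_sizes[j] > 0) {
          x[starts[j]:stops[j], labels == j] <-
            x[starts[j]:stops[j], labels == j] + config$effect_size
        }
      }
    }
    x <- pmax(x, 0)
  })
  dimnames(x) <- list(sprintf("G%05d", seq_len(p)), names(labels))
  list(expression = x, true_labels = labels)
}

#' Generate subtype-linked clinical covariates
#'
#' Immunocompromise is Bernoulli with per-subtype prevalence; ANC and ALC
#' are log-normal with subtype-specific location shifts (subtype 1
#' lymphocyte-rich, subtype 2 neutrophil-rich); PRISM III is a discrete
#' non-negative severity score independent of subtype; gas exchange at
#' 24 h improves faster in subtypes 2-3 than subtype 1.
#'
#' @param true_labels Named integer vector of subtype labels (1..k).
#' @param config A [simulation_config()].
#' @return Validated clinical table, one row per subject.
#' @export
generate_clinical <- function(true_labels, config) {
  config <- validate_config(config)
  if (length(true_labels) != config$n_subjects) {
    stop_domain("true_labels must cover every subject")
  }
  n <- length(true_labels)
  k <- config$k_true
  lab <- as.integer(true_labels)
  shift_pick <- function(shifts) shifts[pmin(lab, length(shifts))]
  withr::with_seed(sub_seed(config$seed, "clinical"), {
    immuno <- rbinom(n, 1, config$immunocompromised_prev[lab]) == 1
    sct <- immuno & rbinom(n, 1, 0.5) == 1
    etiology <- sample(ETIOLOGY_LEVELS, n, replace = TRUE,
                       prob = c(0.58, 0.20, 0.10, 0.03, 0.09))
    anc_shift <- shift_pick(c(0, 0.25, 0.10))
    alc_shift <- shift_pick(c(0.35, 0, 0))
    pf24_med <- shift_pick(c(180, 235, 250))
    oi24_med <- shift_pick(c(9.8, 5.7, 6.0))
    df <- data.frame(
      subject_id = names(true_labels),
      age = pmin(pmax(rlnorm(n, log(6), 0.9), 0.1), 17.9),
      sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.4, 0.6)),
      prism_iii = rnbinom(n, mu = 12, size = 3),
      nonpulm_organ_failures = rpois(n, 1.5),
      immunocompromised = immuno,
      stem_cell_transplant = sct,
      etiology_direct = etiology %in% c("infectious pneumonia", "aspiration", "trauma"),
      etiology_infectious = etiology %in% c("infectious pneumonia", "nonpulmonary sepsis"),
      etiology_category = etiology,
      anc = rlnorm(n, log(6000) + anc_shift, 0.7),
      alc = rlnorm(n, log(1200) + alc_shift, 0.8),
      pf_onset = pmin(pmax(rlnorm(n, log(150), 0.45), 40), 300),
      pf_24h = pmin(pmax(rlnorm(n, log(pf24_med), 0.4), 40), 450),
      oi_onset = pmin(pmax(rlnorm(n, log(11.5), 0.5), 1), 60),
      oi_24h = pmin(pmax(rlnorm(n, log(oi24_med), 0.5), 1), 60),
      dopamine = rbinom(n, 1, 0.30) * rgamma(n, 2, scale = 3),
      dobutamine = rbinom(n, 1, 0.10) * rgamma(n, 2, scale = 3),
      epinephrine = rbinom(n, 1, 0.25) * rgamma(n, 1.5, scale = 0.05),
      norepinephrine = rbinom(n, 1, 0.20) * rgamma(n, 1.5, scale = 0.05),
      phenylephrine = rbinom(n, 1, 0.05) * rgamma(n, 1.5, scale = 0.05),
      milrinone = rbinom(n, 1, 0.15) * rgamma(n, 2, scale = 0.25),
      vasopressin = rbinom(n, 1, 0.10) * rgamma(n, 1.5, scale = 4e-4),
      stringsAsFactors = FALSE)
  })
  validate_clinical(df)
}

#' Simulate competing-risk extubation/death data with planted effects
#'
#' Uses the indirect subdistribution parameterization with sustained
#' extubation as the event of interest: the probability of ever being
#' extubated is `1 - (1 - p_base)^exp(eta)`, with conditional event times
#' drawn from the implied subdistribution so that the extubation
#' subdistribution hazard ratio between two covariate patterns is exactly
#' `exp(eta_1 - eta_2)`. Subjects on the competing path die at a
#' truncated-exponential time within the horizon; extubation times beyond
#' the horizon are administratively censored.
#'
#' @param eta Linear predictor of the extubation subdistribution model
#'   (length n).
#' @param p_base Baseline (eta = 0) probability of ever being extubated,
#'   in (0, 1).
#' @param rate Daily rate of the baseline extubation-time law.
#' @param death_rate Daily rate of the truncated death-time law.
#' @param horizon Administrative censoring day (default 28).
#' @param seed Optional seed.
#' @return Data frame with `time` in (0, horizon] and `event` (0 censored,
#'   1 extubated alive, 2 died).
#' @export
simulate_competing_risks <- function(eta, p_base, rate, death_rate = 0.1,
                                     horizon = EVENT_HORIZON, seed = NULL) {
  if (p_base <= 0 || p_base >= 1) stop_domain("p_base must lie in (0, 1)")
  draw <- function() {
    n <- length(eta)
    g <- exp(eta)
    mass1 <- 1 - (1 - p_base)^g
    is_ext <- rbinom(n, 1, mass1) == 1
    time <- numeric(n)
    event <- integer(n)
    if (any(is_ext)) {
      v <- runif(sum(is_ext)) * mass1[is_ext]
      q <- (1 - (1 - v)^(1 / g[is_ext])) / p_base
      t1 <- -log(1 - q) / rate
      cen <- t1 > horizon
      time[is_ext] <- pmin(t1, horizon)
      event[is_ext] <- ifelse(cen, 0L, 1L)
    }
    if (any(!is_ext)) {
      m <- sum(!is_ext)
      u <- runif(m)
      t2 <- -log(1 - u * (1 - exp(-death_rate * horizon))) / death_rate
      time[!is_ext] <- t2
      event[!is_ext] <- 2L
    }
    data.frame(time = time, event = event)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate competing-risk ventilation outcomes per subtype
#'
#' Death by day 28 occurs with the per-subtype probability
#' `death_prob_28d`; survivors of the competing path are extubated at
#' times from the indirect subdistribution law of
#' [simulate_competing_risks()], so that (when all death probabilities lie
#' strictly in (0, 1)) the true extubation log-SHR of subtype j versus
#' subtype 1 equals `log(log(dp_j) / log(dp_1))` (see
#' [implied_extubation_loghr()]). A fraction of extubated survivors is
#' reintubated more than 24 h later, adding ventilator days without moving
#' the sustained-liberation event time.
#'
#' @param true_labels Named integer vector of subtype labels.
#' @param config A [simulation_config()].
#' @return Validated events table (one row per ventilation interval).
#' @export
generate_outcomes <- function(true_labels, config) {
  config <- validate_config(config)
  if (length(true_labels) != config$n_subjects) {
    stop_domain("true_labels must cover every subject")
  }
  lab <- as.integer(true_labels)
  dp <- config$death_prob_28d
  horizon <- EVENT_HORIZON
  withr::with_seed(sub_seed(config$seed, "outcomes"), {
    if (all(dp == 0)) {
      t1 <- rexp(length(lab), config$extubation_rate)
      cr <- data.frame(time = pmin(t1, horizon),
                       event = ifelse(t1 > horizon, 0L, 1L))
    } else if (all(dp > 0 & dp < 1)) {
      eta <- log(log(dp[lab]) / log(dp[1]))
      cr <- simulate_competing_risks(eta, p_base = 1 - dp[1],
                                     rate = config$extubation_rate,
                                     horizon = horizon)
    } else {
      # mixed zero/positive masses: per-subtype independent draws
      die <- rbinom(length(lab), 1, dp[lab]) == 1
      t1 <- rexp(length(lab), config$extubation_rate)
      td <- -log(1 - runif(length(lab)) * (1 - exp(-0.1 * horizon))) / 0.1
      cr <- data.frame(
        time = ifelse(die, td, pmin(t1, horizon)),
        event = ifelse(die, 2L, ifelse(t1 > horizon, 0L, 1L)))
    }
    rows <- lapply(seq_along(lab), function(i) {
      sid <- names(true_labels)[i]
      ti <- cr$time[i]; ev <- cr$event[i]
      if (ev == 2L) {
        data.frame(subject_id = sid, vent_start = 0, vent_end = ti,
                   death_day = ti, picu_survivor = FALSE)
      } else if (ev == 0L) {
        data.frame(subject_id = sid, vent_start = 0, vent_end = horizon,
                   death_day = NA_real_, picu_survivor = TRUE)
      } else {
        df <- data.frame(subject_id = sid, vent_start = 0, vent_end = ti,
                         death_day = NA_real_, picu_survivor = TRUE)
        if (runif(1) < config$reintubation_prob) {
          gap <- 1 + 0.25 + rexp(1, 1 / 2)
          len <- 0.5 + rexp(1, 1 / 2)
          if (ti + gap + len <= horizon) {
            df <- rbind(df, data.frame(
              subject_id = sid, vent_start = ti + gap,
              vent_end = ti + gap + len,
              death_day = NA_real_, picu_survivor = TRUE))
          }
        }
        df
      }
    })
    ev <- do.call(rbind, rows)
  })
  validate_events(ev)
}

#' True extubation log-SHR implied by per-subtype death probabilities
#'
#' @param death_prob_28d Per-subtype death probabilities, all in (0, 1).
#' @return Log subdistribution hazard ratios versus subtype 1.
#' @export
implied_extubation_loghr <- function(death_prob_28d) {
  if (any(death_prob_28d <= 0 | death_prob_28d >= 1)) {
    stop_domain("implied log-SHR requires death probabilities in (0, 1)")
  }
  log(log(death_prob_28d) / log(death_prob_28d[1]))
}

#' Simulate a complete synthetic cohort
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort` list: `expression`, `clinical`, `events`,
#'   `true_labels`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  config <- validate_config(config)
  expr <- generate_expression(config)
  clinical <- generate_clinical(expr$true_labels, config)
  events <- generate_outcomes(expr$true_labels, config)
  out <- list(expression = expr$expression, clinical = clinical,
              events = events, true_labels = expr$true_labels,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes expression TSV, clinical CSV, events CSV, true-label CSV and a
#' JSON sidecar echoing the full simulation configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(
    write_expression(cohort$expression, file.path(dir, "expression.tsv")),
    write_clinical(cohort$clinical, file.path(dir, "clinical.csv")),
    write_events(cohort$events, file.path(dir, "events.csv")))
  write.csv(data.frame(subject_id = names(cohort$true_labels),
                       subtype = as.integer(cohort$true_labels)),
            file.path(dir, "true_labels.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(p, file.path(dir, c("true_labels.csv", "sim_config.json"))))
}
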