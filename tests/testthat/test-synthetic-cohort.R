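test_that("configuration invariants are enforced with named errors", {
  expect_error(simulation_config(n_informative = 5000), "n_informative")
  expect_error(simulation_config(subtype_proportions = c(0.5, 0.4)), "subtype_proportions")
  expect_error(simulation_config(immunocompromised_prev = c(0.2, 1.4, 0.1)),
               "immunocompromised_prev")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(death_prob_28d = c(-0.1, 0.2, 0.3)), "death_prob_28d")
})

test_that("identical configurations produce identical cohorts", {
  a <- simulate_cohort(small_config(seed = 9))
  b <- simulate_cohort(small_config(seed = 9))
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$events, b$events)
  c <- simulate_cohort(small_config(seed = 10))
  expect_false(identical(a$expression, c$expression))
})

test_that("subjects are apportioned to subtypes by largest remainder", {
  cfg <- simulation_config(n_subjects = 96, subtype_proportions = c(31, 29, 36) / 96)
  lab <- generate_expression(cfg)$true_labels
  expect_equal(unname(table(lab)), c(31L, 29L, 36L), ignore_attr = TRUE)
  # proportions that do not divide n still give sizes summing to n
  cfg2 <- small_config(n_subjects = 10, subtype_proportions = c(1, 1, 1) / 3)
  lab2 <- generate_expression(cfg2)$true_labels
  expect_equal(sum(table(lab2)), 10L)
  expect_equal(max(table(lab2)) - min(table(lab2)), 1L)
})

test_that("informative blocks shift each subtype's mean by the effect size", {
  cfg <- small_config(n_subjects = 300, n_genes = 90, n_informative = 30,
                      subtype_proportions = c(100, 100, 100) / 300,
                      effect_size = 2, seed = 2)
  ge <- generate_expression(cfg)
  x <- ge$expression
  # block 1 (genes 1-10) is elevated in subtype 1 only
  in1 <- rowMeans(x[1:10, ge$true_labels == 1])
  out1 <- rowMeans(x[1:10, ge$true_labels != 1])
  expect_equal(mean(in1 - out1), 2, tolerance = 0.15)
  # non-informative genes are exchangeable across subtypes
  null_diff <- mean(rowMeans(x[31:90, ge$true_labels == 1]) -
                    rowMeans(x[31:90, ge$true_labels != 1]))
  expect_lt(abs(null_diff), 0.1)
  expect_true(all(x >= 0))
})

test_that("zero effect size leaves no recoverable structure", {
  aris <- vapply(1:50, function(s) {
    cfg <- small_config(n_subjects = 48, n_genes = 150, n_informative = 60,
                        subtype_proportions = c(16, 16, 16) / 48,
                        effect_size = 0, seed = s)
    ge <- generate_expression(cfg)
    fit <- kmeans_cluster(t(ge$expression), 3, n_init = 5, seed = s)
    ari(fit$labels, ge$true_labels)
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.03)
})

test_that("recovery improves monotonically with effect size", {
  grid <- c(0, 0.5, 1, 2)
  mean_ari <- vapply(grid, function(eff) {
    mean(vapply(1:12, function(s) {
      cfg <- small_config(n_subjects = 60, n_genes = 300, n_informative = 90,
                          effect_size = eff, seed = 100 + s)
      ge <- generate_expression(cfg)
      fit <- kmeans_cluster(t(ge$expression), 3, n_init = 5, seed = s)
      ari(fit$labels, ge$true_labels)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= -1e-8))
  expect_gt(mean_ari[4], 0.9)
})

test_that("clinical covariates are calibrated to their subtype parameters", {
  cfg <- simulation_config(n_subjects = 4500, n_genes = 5, n_informative = 0,
                           subtype_proportions = c(1, 1, 1) / 3,
                           immunocompromised_prev = c(0.32, 0.48, 0.14), seed = 5)
  lab <- true_labels <- generate_expression(cfg)$true_labels
  clin <- generate_clinical(lab, cfg)
  for (j in 1:3) {
    sel <- lab == j
    p_hat <- mean(clin$immunocompromised[sel])
    p <- cfg$immunocompromised_prev[j]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(p_hat - p), 3 * se)
  }
  # SCT implies immunocompromised
  expect_true(all(clin$immunocompromised[clin$stem_cell_transplant]))
  # zero prevalence means zero flags
  cfg0 <- simulation_config(n_subjects = 300, n_genes = 5, n_informative = 0,
                            subtype_proportions = c(1, 1, 1) / 3,
                            immunocompromised_prev = c(0, 0, 0), seed = 6)
  expect_true(!any(generate_clinical(generate_expression(cfg0)$true_labels,
                                     cfg0)$immunocompromised))
  expect_identical(generate_clinical(lab, cfg), clin)  # determinism
})

test_that("28-day death fractions converge to the configured probabilities", {
  cfg <- simulation_config(n_subjects = 5000, n_genes = 5, n_informative = 0,
                           subtype_proportions = c(1, 1, 1) / 3,
                           death_prob_28d = c(0.32, 0.24, 0.08), seed = 7)
  lab <- generate_expression(cfg)$true_labels
  ev <- generate_outcomes(lab, cfg)
  es <- events_summary(ev)
  died <- !es$picu_survivor[match(names(lab), es$subject_id)]
  for (j in 1:3) {
    p <- cfg$death_prob_28d[j]
    se <- sqrt(p * (1 - p) / sum(lab == j))
    expect_lt(abs(mean(died[lab == j]) - p), 3 * se)
  }
})

test_that("every subject resolves to exactly one of the three outcome states", {
  co <- simulate_cohort(small_config(n_subjects = 200, n_genes = 10, n_informative = 0,
                                     subtype_proportions = c(1, 1, 1) / 3, seed = 8))
  es <- events_summary(co$events)
  expect_equal(nrow(es), 200L)
  expect_true(all(es$event %in% 0:2))
  expect_true(all(es$time > 0 & es$time <= 28))
  expect_true(all(es$event[!es$picu_survivor] == 2L))
  expect_true(all(es$vfd[!es$picu_survivor] == 0L))
})

test_that("zero death probability removes competing events entirely", {
  cfg <- small_config(n_subjects = 150, n_genes = 10, n_informative = 0,
                      subtype_proportions = c(1, 1, 1) / 3,
                      death_prob_28d = c(0, 0, 0), seed = 9)
  ev <- generate_outcomes(generate_expression(cfg)$true_labels, cfg)
  es <- events_summary(ev)
  expect_true(all(es$event %in% c(0L, 1L)))
  expect_true(all(es$picu_survivor))
})

test_that("null covariate effects yield subdistribution hazard ratios near 1", {
  covered <- vapply(1:100, function(s) {
    x <- rbinom(150, 1, 0.5)
    d <- simulate_competing_risks(rep(0, 150), p_base = 0.75, rate = 0.12,
                                  seed = 2000 + s)
    fit <- fit_fine_gray(d$time, d$event, data.frame(x = x))
    cf <- fit$coefficients
    cf$ci_low <= 1 && 1 <= cf$ci_high
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("a written cohort reads back identically", {
  co <- simulate_cohort(small_config(n_subjects = 12, n_genes = 30, n_informative = 9,
                                     subtype_proportions = c(4, 4, 4) / 12))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_equal(read_expression(file.path(dir, "expression.tsv")), co$expression)
  expect_equal(read_clinical(file.path(dir, "clinical.csv"))$alc, co$clinical$alc)
  cfg_back <- jsonlite::read_json(file.path(dir, "sim_config.json"),
                                  simplifyVector = TRUE)
  expect_equal(cfg_back$seed, co$config$seed)
})
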