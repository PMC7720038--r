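test_that("logistic odds ratios reproduce the 2x2 closed form", {
  set.seed(1)
  for (i in 1:10) {
    tab <- matrix(sample(3:30, 4), 2)  # a b / c d, no zero cells
    x <- rep(c(0, 1), c(tab[1, 1] + tab[2, 1], tab[1, 2] + tab[2, 2]))
    y <- c(rep(1, tab[1, 1]), rep(0, tab[2, 1]),
           rep(1, tab[1, 2]), rep(0, tab[2, 2]))
    fit <- fit_logistic(y, data.frame(x = x))
    cf <- fit$coefficients
    or_closed <- (tab[1, 2] * tab[2, 1]) / (tab[1, 1] * tab[2, 2])
    expect_equal(cf$ratio[cf$term == "x"], or_closed, tolerance = 1e-6)
  }
})

test_that("logistic regression is calibrated under the null", {
  set.seed(2)
  x <- rnorm(400)
  y <- rbinom(400, 1, 0.5)
  fit <- fit_logistic(y, data.frame(x = x))
  cf <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(cf$estimate), 3 * cf$se)
  expect_true(cf$ci_low < 1 && cf$ci_high > 1)
  expect_true(fit$converged)
})

test_that("separation and rank deficiency raise explicit errors", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_error(fit_logistic(y, data.frame(x = x)), "separation")
  xx <- data.frame(a = 1:8, b = 2 * (1:8))
  expect_error(fit_logistic(rep(c(0, 1), 4), xx), "rank deficient")
  expect_error(fit_logistic(c(0, 1, 2), data.frame(x = 1:3)), "binary")
})

test_that("Cox fit maximizes the hand-coded Breslow partial likelihood", {
  set.seed(3)
  n <- 40
  x <- rnorm(n)
  t0 <- rexp(n, exp(0.6 * x) * 0.2)
  ev <- as.numeric(t0 < 10)
  tt <- pmin(t0, 10)
  fit <- fit_cox(tt, ev, data.frame(x = x))
  # independent oracle: maximize the Breslow log partial likelihood directly
  logpl <- function(b) {
    lp <- b * x
    sum(vapply(which(ev == 1), function(i) {
      risk <- tt >= tt[i]
      lp[i] - log(sum(exp(lp[risk])))
    }, numeric(1)))
  }
  b_opt <- optimize(logpl, c(-3, 3), maximum = TRUE)$maximum
  expect_equal(fit$coefficients$estimate, b_opt, tolerance = 1e-4)
})

test_that("Fine-Gray reduces to Cox when competing events are absent", {
  set.seed(4)
  for (i in 1:10) {
    n <- 150
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    t0 <- rexp(n, exp(0.4 * x[, 1] - 0.3 * x[, 2]) * 0.1)
    ev <- ifelse(t0 > 28, 0, 1)
    tt <- pmin(t0, 28)
    fg <- fit_fine_gray(tt, ev, x)
    cx <- fit_cox(tt, ev, x)
    expect_lt(max(abs(fg$coefficients$estimate - cx$coefficients$estimate)), 1e-6)
  }
})

test_that("Fine-Gray input contracts are enforced", {
  d <- simulate_competing_risks(rep(0, 50), 0.7, 0.1, seed = 1)
  expect_error(fit_fine_gray(d$time, rep(2L, 50), data.frame(x = rnorm(50))),
               "no events of interest")
  expect_error(fit_fine_gray(c(-1, d$time[-1]), d$event,
                             data.frame(x = rnorm(50))), "positive")
  expect_error(fit_fine_gray(d$time, rep(5L, 50), data.frame(x = rnorm(50))),
               "0/1/2")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(0, 1, 2, 3))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  expect_true(all(km_estimate(c(2, 5, 7), c(0, 0, 0))$survival == 1))
  expect_equal(step_at(km, c(0.5, 1.5, 10), v0 = 1), c(1, 2 / 3, 0))
})

test_that("log-rank matches hand computation and is symmetric in labels", {
  # group A events at (1, 2); group B censored at (3, 3)
  # O-E = 7/6, V = 17/36, chi-square = 49/17 by hand
  r <- logrank_test(c(1, 2, 3, 3), c(1, 1, 0, 0), c("A", "A", "B", "B"))
  expect_equal(r$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(r$df, 1)

  set.seed(5)
  tt <- rexp(40, 0.2); ev <- rbinom(40, 1, 0.8); g <- rep(1:2, 20)
  r1 <- logrank_test(tt, ev, g)
  r2 <- logrank_test(tt, ev, 3 - g)
  expect_equal(r1$statistic, r2$statistic)

  r3 <- logrank_test(rexp(60, 0.2), rbinom(60, 1, 0.7), rep(1:3, 20),
                     pairwise = TRUE)
  expect_equal(nrow(r3$pairwise), 3L)
  expect_error(logrank_test(tt, ev, rep(1, 40)), "2 non-empty groups")
})

test_that("log-rank p-values are calibrated under the null", {
  set.seed(6)
  rej <- mean(replicate(2000, {
    tt <- rexp(60, 0.15)
    ev <- as.numeric(tt < 20)
    logrank_test(pmin(tt, 20), ev, rep(1:2, 30))$p_value <= 0.05
  }))
  expect_gt(rej, 0.030)
  expect_lt(rej, 0.070)
})

test_that("cumulative incidence matches hand Aalen-Johansen and sums to one", {
  # 4 subjects: cause 1 at t=1, cause 2 at t=2, cause 1 at t=3, censored at 4
  ci <- cumulative_incidence(c(1, 2, 3, 4), c(1L, 2L, 1L, 0L))
  expect_equal(step_at(ci[["1"]], 28, v0 = 0), 0.5)
  expect_equal(step_at(ci[["2"]], 28, v0 = 0), 0.25)

  # single cause: CIF = 1 - KM
  set.seed(7)
  tt <- rexp(50, 0.2); ev <- rbinom(50, 1, 0.7)
  ci1 <- cumulative_incidence(pmin(tt, 28), as.integer(ev))
  km <- km_estimate(pmin(tt, 28), ev)
  at <- sort(unique(tt[ev == 1]))
  expect_equal(step_at(ci1[["1"]], at, v0 = 0), 1 - step_at(km, at, v0 = 1),
               tolerance = 1e-12)

  # competing causes: CIF1 + CIF2 + S = 1 at all jump times
  d <- simulate_competing_risks(rnorm(200) * 0.5, 0.7, 0.12, seed = 8)
  ci2 <- cumulative_incidence(d$time, d$event)
  s_all <- attr(ci2, "overall_survival")
  at <- sort(unique(d$time[d$event != 0]))
  total <- step_at(ci2[["1"]], at, v0 = 0) + step_at(ci2[["2"]], at, v0 = 0) +
    step_at(s_all, at, v0 = 1)
  expect_equal(total, rep(1, length(at)), tolerance = 1e-12)

  # no events at all: empty cause list, survival identically 1
  ci0 <- cumulative_incidence(c(2, 3), c(0L, 0L))
  expect_length(ci0, 0)
})

test_that("outcome models run across all adjustment presets on a cohort", {
  co <- simulate_cohort(small_config(n_subjects = 90, seed = 6,
                                     subtype_proportions = c(30, 30, 30) / 90))
  t2 <- fit_outcome_models(co$clinical, co$true_labels, co$events)
  expect_setequal(unique(t2$adjustment), names(adjustment_presets()))
  expect_setequal(unique(t2$model), c("mortality_logistic", "extubation_fine_gray"))
  ok <- t2$note == ""
  expect_true(all(t2$ci_low[ok] < t2$ratio[ok] & t2$ratio[ok] < t2$ci_high[ok]))
  expect_error(fit_outcome_models(co$clinical, co$true_labels, co$events,
                                  adjust = "nope"), "unknown adjustment")
})
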