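test_that("Cox coefficient matches the Efron grid-search oracle", {
  # deaths alternate between covariate levels, so the MLE is finite
  time <- c(2, 4, 6, 8); event <- c(1, 1, 1, 1); x <- c(1, 0, 0, 1)
  fit <- cox_fit(time, event, x)
  beta_grid <- oracle_cox_grid(time, event, x)
  expect_equal(unname(attr(fit, "coef")["gene"]), beta_grid, tolerance = 1e-3)

  # with ties, against the same grid on a second dataset
  time2 <- c(1, 1, 2, 3, 5, 5, 7, 9); event2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  x2 <- c(0.5, -1, 0.2, 1.1, -0.3, 0.8, -0.6, 0.1)
  fit2 <- cox_fit(time2, event2, x2)
  expect_equal(unname(attr(fit2, "coef")["gene"]),
               oracle_cox_grid(time2, event2, x2), tolerance = 1e-3)
})

test_that("Cox fit agrees with survival::coxph (Efron ties)", {
  skip_if_not_installed("survival")
  set.seed(61)
  n <- 120
  x <- stats::rnorm(n)
  time <- stats::rexp(n, rate = exp(0.5 * x))
  event <- stats::rbinom(n, 1, 0.8)
  fit <- cox_fit(time, event, x)
  ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_equal(unname(attr(fit, "coef")["gene"]), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$p, summary(ref)$coefficients[1, "Pr(>|z|)"],
               tolerance = 1e-6)
  # age adjustment: the reported HR stays the gene's
  age <- stats::rnorm(n, 60, 8)
  fit2 <- cox_fit(time, event, x, age = age)
  ref2 <- survival::coxph(survival::Surv(time, event) ~ x + age,
                          ties = "efron")
  expect_equal(fit2$hr, unname(exp(stats::coef(ref2)["x"])), tolerance = 1e-6)
  expect_true(fit2$adjusted_for_age)
})

test_that("Cox recovers a planted log hazard of 0.7 at n = 500", {
  set.seed(62)
  n <- 500
  x <- stats::rnorm(n)
  time <- stats::rexp(n, rate = 0.01 * exp(0.7 * x))
  cens <- stats::runif(n, 0, 300)
  fit <- cox_fit(pmin(time, cens), as.integer(time <= cens), x)
  expect_equal(log(fit$hr), 0.7, tolerance = 0.15)
})

test_that("Cox errors on degenerate inputs", {
  expect_error(cox_fit(1:4, c(1, 1, 1, 1), rep(2, 4)), "constant")
  expect_error(cox_fit(1:4, c(0, 0, 0, 1), 1:4), "2 events")
  # perfect separation: monotone likelihood flagged
  expect_error(cox_fit(c(1, 2, 3, 4, 5, 6), rep(1, 6),
                       c(3, 2.5, 2, 1, 0.5, 0)),
               "separation|singular|diverged")
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)  # risk set of 1 at t = 3
  expect_equal(km_estimate(c(5, 7, 9), c(0, 0, 0))$surv, c(1, 1, 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("Kaplan-Meier equals the empirical survival with no censoring", {
  set.seed(71)
  t <- stats::rexp(50)
  km <- km_estimate(t, rep(1, 50))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
  # and matches the row-by-row oracle under censoring
  ev <- stats::rbinom(50, 1, 0.6)
  km2 <- km_estimate(t, ev)
  expect_equal(km2$surv, oracle_km(t, ev)$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches a hand-computed table and survdiff", {
  # identical groups: statistic 0, p 1
  t <- c(1, 2, 3, 1, 2, 3); e <- rep(1, 6); g <- rep(c("a", "b"), each = 3)
  r0 <- logrank_test(t, e, g)
  expect_equal(r0$stat, 0)
  expect_equal(r0$p, 1)
  # A deaths at 1,2; B deaths at 3,4 — four-row O-E/V table by hand:
  # t=1: n=4,n_A=2,d=1 -> e_A=0.5, v=4*... accumulate O-E = (1-.5)+(1-2/3)+0+0
  r <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  o_minus_e <- (1 - 2 / 4) + (1 - 1 / 3) + (0 - 0) + (0 - 0)
  v <- (2 / 4) * (2 / 4) * (4 - 1) / (4 - 1) * 1 + (1 / 3) * (2 / 3) * 1
  expect_equal(r$effect, o_minus_e, tolerance = 1e-12)
  expect_equal(r$stat, o_minus_e^2 / v, tolerance = 1e-12)
  skip_if_not_installed("survival")
  set.seed(81)
  t2 <- stats::rexp(60); e2 <- stats::rbinom(60, 1, 0.7)
  g2 <- rep(c("x", "y"), 30)
  sd <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(logrank_test(t2, e2, g2)$stat, sd$chisq, tolerance = 1e-9)
})

test_that("log-rank is invariant to time scaling and needs two groups", {
  set.seed(91)
  t <- stats::rexp(40); e <- stats::rbinom(40, 1, 0.8); g <- rep(1:2, 20)
  expect_equal(logrank_test(t, e, g)$stat, logrank_test(t * 7.3, e, g)$stat)
  expect_error(logrank_test(t, e, rep(1, 40)), "2 groups")
})

test_that("Cox null 95% CI covers HR = 1 in at least 90 of 100 seeds", {
  cover <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 100
    x <- stats::rnorm(n)
    time <- stats::rexp(n)
    cens <- stats::runif(n, 0, 3)
    fit <- cox_fit(pmin(time, cens), as.integer(time <= cens), x)
    fit$ci_low <= 1 && 1 <= fit$ci_high
  }, logical(1))
  expect_gte(sum(cover), 90)
})
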