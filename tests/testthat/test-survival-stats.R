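test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  # deaths at 2 and 4, no censoring
  km <- km_estimate(c(2, 4))
  expect_equal(km$time, c(2, 4))
  expect_equal(km$survival, c(0.5, 0))

  # deaths {2, 5}, censored {3}: S(2) = 2/3, S(5) = 0
  km2 <- km_estimate(c(2, 5, 3), c(1, 1, 0))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km2$n_risk, c(3, 1))

  # all censored: no death times, curve stays at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3), 0)

  expect_error(km_estimate(numeric(0)), "no survival records")
  expect_error(km_estimate(c(-1, 2)), "finite")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(71)
  for (i in 1:5) {
    t <- round(stats::rweibull(40, 2, 10), 1)  # force ties
    km <- km_estimate(t)
    emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp)
  }
})

test_that("KM agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(72)
  t <- stats::rweibull(60, 3, 10)
  e <- as.integer(stats::runif(60) > 0.25)
  km <- km_estimate(t, e)
  fit <- survival::survfit(survival::Surv(t, e) ~ 1)
  sv <- summary(fit, times = km$time)
  expect_equal(km$survival, sv$surv, tolerance = 1e-10)
  # restricted mean
  tab <- summary(fit, rmean = max(t))$table
  expect_equal(mean_survival(t, e), unname(tab["rmean"]), tolerance = 1e-8)
})

test_that("mean survival is the arithmetic mean without censoring, restricted mean with", {
  expect_equal(mean_survival(c(10, 20, 30)), 20)
  expect_equal(mean_survival(7), 7)
  # step-function area oracle: 1 * 2 + (2/3) * 3 = 4
  expect_equal(mean_survival(c(2, 5, 3), c(1, 1, 0)), 4)
})

test_that("fraction alive handles censoring and endpoints", {
  t <- c(rep(2, 5), rep(12, 15))
  expect_equal(fraction_alive(t, t = 10), 0.75)
  expect_equal(fraction_alive(t, t = 0), 1)
  expect_equal(fraction_alive(1:10, t = 5), 0.5)
  # animals censored before t drop out of the denominator
  expect_equal(fraction_alive(c(2, 12, 12), c(0, 1, 1), t = 10), 1)
})

test_that("log-rank test matches the hand oracle and the survival package", {
  # identical groups: observed = expected everywhere
  res0 <- logrank_test(c(2, 4, 6), rep(1, 3), c(2, 4, 6), rep(1, 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # A deaths {1,2,3}, B deaths {4,5,6}: per-event-time O-E = 1.85,
  # hypergeometric variance 0.6775, chi-square 1.85^2 / 0.6775
  res <- logrank_test(c(1, 2, 3), rep(1, 3), c(4, 5, 6), rep(1, 3))
  expect_equal(res$statistic, 1.85^2 / 0.6775, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pchisq(1.85^2 / 0.6775, 1,
                                          lower.tail = FALSE))

  skip_if_not_installed("survival")
  set.seed(81)
  for (i in 1:5) {
    g <- two_arm(25, 10, 13)
    ea <- as.integer(stats::runif(25) > 0.2)
    eb <- as.integer(stats::runif(25) > 0.2)
    mine <- logrank_test(g$a, ea, g$b, eb)
    ref <- survival::survdiff(
      survival::Surv(c(g$a, g$b), c(ea, eb)) ~ rep(1:2, each = 25))
    expect_equal(mine$statistic, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("two-sample survival tests are symmetric in group order", {
  set.seed(82)
  g <- two_arm(30, 10, 14)
  for (f in list(logrank_test, gehan_wilcoxon_test)) {
    ab <- f(g$a, rep(1, 30), g$b, rep(1, 30))
    ba <- f(g$b, rep(1, 30), g$a, rep(1, 30))
    expect_equal(ab$statistic, ba$statistic, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
               "at least one observed death")
})

test_that("Gehan-Breslow-Wilcoxon weights early differences", {
  expect_equal(gehan_wilcoxon_test(c(2, 4), rep(1, 2),
                                   c(2, 4), rep(1, 2))$statistic, 0)
  # single death time: the weight is a common constant, so the chi-square
  # statistic reduces to the log-rank statistic exactly
  ta <- c(2, 2, 9, 9)  # deaths at 2 only, censored tails
  ea <- c(1, 1, 0, 0)
  tb <- c(2, 9, 9, 9)
  eb <- c(1, 0, 0, 0)
  expect_equal(gehan_wilcoxon_test(ta, ea, tb, eb)$statistic,
               logrank_test(ta, ea, tb, eb)$statistic, tolerance = 1e-12)

  # early separation with late convergence: Gehan emphasizes the early gap
  set.seed(83)
  a <- c(stats::rweibull(25, 3, 4), stats::rweibull(25, 3, 15))
  b <- stats::rweibull(50, 3, 11)
  gw <- gehan_wilcoxon_test(a, rep(1, 50), b, rep(1, 50))
  lr <- logrank_test(a, rep(1, 50), b, rep(1, 50))
  expect_lt(gw$p_value, lr$p_value)
})

test_that("Dunnett adjustment reduces to the t-test with one group and calibrates against multcomp", {
  set.seed(91)
  ctl <- stats::rnorm(8)
  trt <- stats::rnorm(8, 0.9)
  fit <- anova_dunnett(ctl, list(trt))
  tt <- stats::t.test(trt, ctl, var.equal = TRUE)
  expect_lt(abs(fit$comparisons$p_adj - tt$p.value), 0.005)

  # groups identical to control: all adjusted p = 1
  same <- anova_dunnett(c(1, 2, 3, 4), list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_true(all(same$comparisons$p_adj == 1))

  expect_error(anova_dunnett(c(1, 2), list(c(1))), "at least 2")

  skip_if_not_installed("multcomp")
  set.seed(92)
  y <- c(stats::rnorm(10), stats::rnorm(10, 0.5), stats::rnorm(10, 1.2),
         stats::rnorm(10, -0.3))
  grp <- factor(rep(c("ctl", "g1", "g2", "g3"), each = 10))
  mine <- anova_dunnett(y[grp == "ctl"],
                        list(g1 = y[grp == "g1"], g2 = y[grp == "g2"],
                             g3 = y[grp == "g3"]))
  mc <- multcomp::glht(stats::aov(y ~ grp),
                       linfct = multcomp::mcp(grp = "Dunnett"))
  ref <- summary(mc, test = multcomp::adjusted("single-step"))
  expect_equal(unname(mine$comparisons$p_adj),
               unname(as.vector(ref$test$pvalues)), tolerance = 0.01)
})

test_that("Student's and Welch's t behave at the edges and match the pooled oracle", {
  eq <- students_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # pooled-variance closed form: t = -3 / sqrt(1 * (1/3 + 1/3))
  st <- students_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(st$statistic), 3.674235, tolerance = 1e-6)
  expect_equal(st$p_value, 0.0213116411, tolerance = 1e-6)

  # degenerate zero-variance conventions
  expect_equal(students_t(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(students_t(c(2, 2, 2), c(3, 3))$p_value, 0)

  w <- students_t(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  expect_equal(w$test_name, "welch_t")
  expect_true(w$df < 5)  # Satterthwaite df below pooled df
})
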