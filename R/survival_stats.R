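#' Kaplan-Meier product-limit estimate
#'
#' Censoring ties at an event time follow the right-continuous convention:
#' animals censored at a death time are counted at risk at that time and
#' removed afterwards. Input with no deaths yields the constant curve at 1.
#'
#' @param time positive observation times.
#' @param event 1 = death observed, 0 = censored. May be omitted (all deaths).
#' @return a data.frame of class `survival_curve` with one row per distinct
#'   death time: `time`, `n_risk`, `n_event`, `survival`; attributes `n`
#'   (records) and `max_time` (largest observed time, any status).
#' @examples
#' km_estimate(c(2, 5, 3), c(1, 1, 0))
#' @export
km_estimate <- function(time, event = rep(1L, length(time))) {
  check_survival_input(time, event)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(u) sum(time >= u), numeric(1))
  n_event <- vapply(ut, function(u) sum(time == u & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               survival = surv),
    class = c("survival_curve", "data.frame"),
    n = length(time), max_time = max(time)
  )
}

check_survival_input <- function(time, event) {
  if (length(time) == 0) stopf("no survival records supplied")
  if (length(event) != length(time)) stopf("'time' and 'event' lengths differ")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("survival times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stopf("'event' must be 0 (censored) or 1 (death)")
  invisible(TRUE)
}

#' Mean survival time
#'
#' Without censoring this is the arithmetic mean of the death times. With
#' censoring it is the restricted mean: the area under the Kaplan-Meier step
#' function up to the largest observed time (of any status), the standard
#' estimand when the plotted quantity is "average survival" and censoring is
#' present.
#'
#' @inheritParams km_estimate
#' @return mean survival in the input's time unit.
#' @examples
#' mean_survival(c(10, 20, 30))                  # 20
#' mean_survival(c(2, 5, 3), c(1, 1, 0))         # 1*2 + (2/3)*3 = 4
#' @export
mean_survival <- function(time, event = rep(1L, length(time))) {
  check_survival_input(time, event)
  if (all(event == 1)) return(mean(time))
  curve <- km_estimate(time, event)
  tmax <- attr(curve, "max_time")
  if (nrow(curve) == 0) return(tmax)  # censored-only: S = 1 throughout
  breaks <- c(0, curve$time[curve$time <= tmax], tmax)
  heights <- c(1, curve$survival[curve$time <= tmax])
  sum(heights * diff(breaks))
}

#' Fraction of animals alive at a fixed time
#'
#' Animals censored at or before `t` are excluded from the denominator (their
#' status at `t` is unknown); every animal observed beyond `t` counts as
#' alive, deaths at or before `t` count as dead.
#'
#' @inheritParams km_estimate
#' @param t endpoint time, `>= 0`.
#' @return proportion alive at `t`.
#' @export
fraction_alive <- function(time, event = rep(1L, length(time)), t) {
  check_survival_input(time, event)
  assert_number(t, "t", min = 0)
  excluded <- event == 0 & time <= t
  denom <- sum(!excluded)
  if (denom == 0) return(NA_real_)
  sum(time > t) / denom
}

# Weighted log-rank machinery shared by the Mantel-Cox and Gehan tests.
# At each distinct death time the observed deaths in group A are compared to
# the hypergeometric expectation given the risk sets; ties are handled through
# the exact hypergeometric variance term.
weighted_logrank <- function(time_a, event_a, time_b, event_b,
                             weight = c("logrank", "gehan")) {
  weight <- match.arg(weight)
  check_survival_input(time_a, event_a)
  check_survival_input(time_b, event_b)
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  if (sum(event) == 0)
    stopf("log-rank family tests need at least one observed death")
  ut <- sort(unique(time[event == 1]))
  n_j <- vapply(ut, function(u) sum(time >= u), numeric(1))
  n1_j <- vapply(ut, function(u) sum(grp_a & time >= u), numeric(1))
  d_j <- vapply(ut, function(u) sum(event == 1 & time == u), numeric(1))
  d1_j <- vapply(ut, function(u) sum(grp_a & event == 1 & time == u),
                 numeric(1))
  w <- if (weight == "gehan") n_j else rep(1, length(ut))
  o_minus_e <- sum(w * (d1_j - d_j * n1_j / n_j))
  keep <- n_j > 1
  v <- sum((w[keep]^2) * d_j[keep] * (n1_j[keep] / n_j[keep]) *
             (1 - n1_j[keep] / n_j[keep]) *
             (n_j[keep] - d_j[keep]) / (n_j[keep] - 1))
  if (v <= 0) {
    stat <- 0
  } else {
    stat <- o_minus_e^2 / v
  }
  list(statistic = stat, o_minus_e = o_minus_e, variance = v)
}

test_result <- function(statistic, p_value, test_name, df = NA_real_,
                        n = NA_integer_) {
  structure(list(statistic = statistic, p_value = p_value,
                 test_name = test_name, df = df, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Log-rank (Mantel-Cox) two-sample survival test
#'
#' Chi-square statistic `(sum(O - E))^2 / Var` with the hypergeometric
#' variance at each death time; p from the chi-square distribution on 1
#' degree of freedom. Symmetric in group order.
#'
#' @param time_a,event_a survival records of group A.
#' @param time_b,event_b survival records of group B.
#' @return a `test_result` (statistic, p_value, test_name, df, n per group).
#' @export
logrank_test <- function(time_a, event_a = rep(1L, length(time_a)),
                         time_b, event_b = rep(1L, length(time_b))) {
  res <- weighted_logrank(time_a, event_a, time_b, event_b, "logrank")
  p <- if (res$variance <= 0) 1 else
    stats::pchisq(res$statistic, df = 1, lower.tail = FALSE)
  test_result(res$statistic, p, "logrank", df = 1,
              n = c(length(time_a), length(time_b)))
}

#' Gehan-Breslow-Wilcoxon two-sample survival test
#'
#' Weighted log-rank with weight equal to the total number at risk at each
#' death time, up-weighting early differences between the curves; p from the
#' chi-square distribution on 1 degree of freedom.
#'
#' @inheritParams logrank_test
#' @return a `test_result`.
#' @export
gehan_wilcoxon_test <- function(time_a, event_a = rep(1L, length(time_a)),
                                time_b, event_b = rep(1L, length(time_b))) {
  res <- weighted_logrank(time_a, event_a, time_b, event_b, "gehan")
  p <- if (res$variance <= 0) 1 else
    stats::pchisq(res$statistic, df = 1, lower.tail = FALSE)
  test_result(res$statistic, p, "gehan_wilcoxon", df = 1,
              n = c(length(time_a), length(time_b)))
}

# Reference sample of max |T| over k equicorrelated t variates, cached by
# (df, correlation structure, draws). The Dunnett correlation with a shared
# control is corr(T_i, T_j) = sqrt(lambda_i * lambda_j) with
# lambda_i = n_i / (n_i + n_0), which factorizes, so the sample can be built
# from one shared normal plus independent residuals.
dunnett_maxt_sample <- function(lambda, df, n_mc, mc_seed) {
  key <- paste(df, paste(round(lambda, 8), collapse = ","), n_mc, mc_seed,
               sep = "|")
  cached <- .stresspan_cache[[key]]
  if (!is.null(cached)) return(cached)
  k <- length(lambda)
  maxt <- with_seed(mc_seed, {
    z0 <- stats::rnorm(n_mc)
    denom <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- rep(0, n_mc)
    for (i in seq_len(k)) {
      ti <- abs((sqrt(lambda[i]) * z0 +
                   sqrt(1 - lambda[i]) * stats::rnorm(n_mc)) / denom)
      m <- pmax(m, ti)
    }
    m
  })
  .stresspan_cache[[key]] <- maxt
  maxt
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Classical one-way ANOVA over control plus treatment groups, followed by
#' two-sided Dunnett-adjusted p-values for each treatment-vs-control contrast.
#' The adjusted p-value `P(max_j |T_j| >= |t_i|)` is evaluated by Monte Carlo
#' over the equicorrelated multivariate t distribution (a fixed internal seed
#' makes results reproducible; the reference sample is cached per design, so
#' repeated calls at the same group sizes cost only the comparison step).
#' With a single treatment group the adjustment reduces to the ordinary
#' two-sided t-test p within Monte-Carlo error.
#'
#' @param control numeric vector of control observations (n >= 2).
#' @param groups list of numeric vectors, one treatment group each (n >= 2).
#'   A single numeric vector is treated as one group.
#' @param n_mc Monte-Carlo draws for the adjustment (default 1e5, adjusted-p
#'   tolerance about 0.005).
#' @param mc_seed internal seed for the Monte-Carlo reference sample.
#' @return list with `f_statistic`, `f_p`, `df` (residual), and `comparisons`
#'   (data.frame: group, estimate, t, p_adj). Assumes homogeneous variances
#'   (pooled mean squared error), as in the classical procedure.
#' @export
anova_dunnett <- function(control, groups, n_mc = 1e5, mc_seed = 104729L) {
  if (is.numeric(groups)) groups <- list(groups)
  if (!is.list(groups) || length(groups) == 0)
    stopf("'groups' must be a non-empty list of numeric vectors")
  all_groups <- c(list(control), groups)
  sizes <- vapply(all_groups, length, integer(1))
  if (any(sizes < 2)) stopf("every group needs at least 2 observations")
  k <- length(groups)
  labels <- names(groups) %||% paste0("group", seq_len(k))
  if (is.null(names(groups)) || any(names(groups) == ""))
    labels <- paste0("group", seq_len(k))

  means <- vapply(all_groups, mean, numeric(1))
  n_tot <- sum(sizes)
  df_res <- n_tot - (k + 1)
  if (df_res < 1) stopf("not enough observations for the residual variance")
  sse <- sum(vapply(all_groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / df_res
  grand <- sum(sizes * means) / n_tot
  ssb <- sum(sizes * (means - grand)^2)
  f_stat <- (ssb / k) / mse
  f_p <- stats::pf(f_stat, k, df_res, lower.tail = FALSE)

  est <- means[-1] - means[1]
  se <- sqrt(mse * (1 / sizes[-1] + 1 / sizes[1]))
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  lambda <- sizes[-1] / (sizes[-1] + sizes[1])
  maxt <- dunnett_maxt_sample(lambda, df_res, n_mc, mc_seed)
  p_adj <- vapply(abs(tval), function(tt) {
    if (!is.finite(tt)) return(0)
    mean(maxt >= tt)
  }, numeric(1))

  list(f_statistic = f_stat, f_p = f_p, df = c(k, df_res),
       comparisons = data.frame(group = labels, estimate = unname(est),
                                t = unname(tval), p_adj = unname(p_adj)))
}

#' Two-sample Student's or Welch's t-test
#'
#' Two-sided by default. When both groups have zero variance and equal means
#' the p-value is 1 by convention (and 0 when the constant means differ),
#' where the textbook statistic is undefined.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param welch use Welch's unequal-variance form with Satterthwaite degrees
#'   of freedom (default `FALSE`: pooled-variance Student's test).
#' @return a `test_result`.
#' @export
students_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stopf("both groups need at least 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(test_result(if (equal) 0 else Inf, if (equal) 1 else 0,
                       if (welch) "welch_t" else "student_t",
                       df = NA_real_, n = c(length(a), length(b))))
  }
  fit <- stats::t.test(a, b, var.equal = !welch)
  test_result(unname(fit$statistic), fit$p.value,
              if (welch) "welch_t" else "student_t",
              df = unname(fit$parameter), n = c(length(a), length(b)))
}
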