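# Survival and group-comparison statistics.

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # all events at 1, 2, 3: S = 2/3, 1/3, 0
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))

  # censored mix {1+, 2, 2, 3+}: S(2) = 1 * (1 - 2/3) = 1/3
  km2 <- km_estimate(c(1, 2, 2, 3), c(0, 1, 1, 0))
  expect_equal(km2$surv[km2$time == 2], 1 / 3)
  expect_equal(km2$surv[km2$time == 3], 1 / 3) # censoring does not drop S

  # without censoring KM equals 1 - ECDF
  set.seed(5)
  t <- rexp(40, 0.1)
  km3 <- km_estimate(t, rep(1, 40))
  expect_equal(km3$surv, 1 - ecdf(t)(km3$time))

  # monotone, right-continuous from S(0) = 1
  expect_true(all(diff(km3$surv) <= 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), class = "tmectx_spec_error")
})

test_that("log-rank test is null on duplicated groups and matches the Cox score", {
  set.seed(11)
  t <- rexp(30, 0.05); e <- rbinom(30, 1, 0.8)
  # duplicated data in two groups: statistic 0
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 30))
  expect_lt(lr0$statistic, 1e-10)

  # two-group statistic equals the Cox partial-likelihood score test at beta = 0
  t2 <- c(1.3, 2.1, 3.7, 4.2, 5.9, 6.4, 7.8, 9.1)
  e2 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g2 <- c(0, 1, 0, 1, 0, 1, 0, 1)
  lr <- logrank_test(t2, e2, g2)
  sc <- survival::coxph(survival::Surv(t2, e2) ~ g2)$score
  expect_equal(lr$statistic, unname(sc), tolerance = 1e-8)

  # invariant under relabelling groups
  lr_swap <- logrank_test(t2, e2, 1 - g2)
  expect_equal(lr$statistic, lr_swap$statistic)
  expect_error(logrank_test(t2, e2, rep("a", 8)), class = "tmectx_data_error")
})

test_that("two-group log-rank permutation p agrees with the asymptotic p", {
  set.seed(19)
  n <- 20
  t <- rexp(n, 0.08); e <- rbinom(n, 1, 0.85); g <- rep(0:1, each = n / 2)
  lr <- logrank_test(t, e, g)
  # permutation reference built from the linear-rank form of the statistic
  a <- logrank_scores(t, e)
  m <- sum(g == 1)
  z_of <- function(gg) {
    s <- sum(a[gg == 1])
    (s - m * mean(a)) / sqrt(m * (n - m) / (n * (n - 1)) * sum((a - mean(a))^2))
  }
  obs <- abs(z_of(g))
  perm <- replicate(1e4, abs(z_of(sample(g))))
  p_perm <- (sum(perm >= obs - 1e-12) + 1) / (1e4 + 1)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(p_perm - lr$p), mc_err + 0.02)
})

test_that("univariate Cox matches an independent partial-likelihood root", {
  # no ties: the score equation can be solved numerically from scratch
  t <- c(1, 2, 3, 4, 5, 6, 7)
  e <- c(1, 1, 1, 0, 1, 1, 0)
  x <- c(0.5, -1.2, 0.3, 1.1, -0.4, 0.9, -0.7)
  score <- function(beta) {
    s <- 0
    for (i in which(e == 1)) {
      risk <- which(t >= t[i])
      w <- exp(beta * x[risk])
      s <- s + x[i] - sum(w * x[risk]) / sum(w)
    }
    s
  }
  root <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  fit <- cox_univariate(t, e, x)
  expect_equal(fit$beta, root, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$hr, exp(fit$beta))
  expect_equal(fit$ci_low, exp(fit$beta - 1.96 * fit$se))

  # degenerate inputs
  expect_error(cox_univariate(t, e, rep(1, 7)), class = "tmectx_data_error")
  expect_error(cox_univariate(t, rep(0, 7), x), class = "tmectx_data_error")

  # monotone likelihood (perfect separation) is flagged, with drift sign
  sep <- cox_univariate(1:10, rep(1, 10), 10:1)
  expect_false(sep$converged)
  expect_equal(sep$drift, 1) # early deaths have high covariate: hazard up
})

test_that("maxstat scan equals the brute-force exhaustive scan", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 40
    x <- round(rnorm(n), 2) # rounding induces ties among covariate values
    t <- rexp(n, 0.1 * exp(-0.5 * (x > 0)))
    e <- rbinom(n, 1, 0.8)
    if (sum(e) == 0) e[1] <- 1
    dic <- maxstat_dichotomize(t, e, x, p_method = "none")
    bf <- brute_force_maxstat(t, e, x)
    expect_equal(dic$statistic, bf$statistic, tolerance = 1e-10)
    expect_equal(dic$cutpoint, bf$cutpoint, tolerance = 1e-10)
    # labels partition the samples within the proportion window
    prop_low <- mean(dic$labels == "low")
    expect_gte(prop_low, 0.1)
    expect_lte(prop_low, 0.9)
  }
})

test_that("maxstat recovers a planted cutpoint and reports its method", {
  set.seed(41)
  n <- 120
  x <- runif(n, 0, 10)
  truth <- 4
  sp <- survival_spec(baseline_median_months = 20,
                      covariate_log_hazards = c(high = log(0.3)),
                      censor_random_rate = 0)
  sv <- generate_survival(sp, data.frame(patient_id = seq_len(n),
                                         high = as.numeric(x > truth)),
                          seed = 2)
  dic <- maxstat_dichotomize(sv$time_months, sv$event, x, p_method = "approx")
  # chosen cutpoint brackets the planted split
  expect_gt(dic$cutpoint, truth - 1)
  expect_lt(dic$cutpoint, truth + 1)
  expect_identical(dic$p_method, "approx")
  expect_lt(dic$p, 0.05)

  perm <- maxstat_dichotomize(sv$time_months, sv$event, x,
                              p_method = "permutation", n_perm = 499)
  expect_identical(perm$p_method, "permutation")
  expect_lt(perm$p, 0.05)

  expect_error(maxstat_dichotomize(sv$time_months, sv$event, rep(1, n)),
               class = "tmectx_data_error")
  expect_error(maxstat_dichotomize(sv$time_months[1:5], sv$event[1:5], x[1:5]),
               class = "tmectx_data_error")
})

test_that("combined dichotomies cross-classify and find co-infiltration effects", {
  expect_equal(combine_dichotomies(c("high", "high"), c("low", "low")),
               c("high/low", "high/low"))
  expect_error(combine_dichotomies(c("high"), c("low", "low")),
               class = "tmectx_spec_error")
  expect_error(combine_dichotomies("yes", "low"), class = "tmectx_spec_error")
  expect_true(is.na(combine_dichotomies(NA_character_, "low")))

  # independent balanced labels: all four groups roughly even
  set.seed(3)
  la <- sample(c("high", "low"), 400, TRUE)
  lb <- sample(c("high", "low"), 400, TRUE)
  tab <- table(combine_dichotomies(la, lb))
  expect_equal(length(tab), 4)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)

  # planted protective co-infiltration: best survival in high/high
  n <- 400
  a <- rep(c(1, 0), each = n / 2)
  b <- rep(c(1, 0), times = n / 2)
  sp <- survival_spec(baseline_median_months = 15,
                      covariate_log_hazards = c(a = log(0.45), b = log(0.45)),
                      censor_random_rate = 0)
  sv <- generate_survival(sp, data.frame(patient_id = seq_len(n), a = a, b = b),
                          seed = 8)
  grp <- combine_dichotomies(ifelse(a == 1, "high", "low"),
                             ifelse(b == 1, "high", "low"))
  med <- tapply(seq_len(n), grp, function(i) km_median(sv$time_months[i],
                                                       sv$event[i]))
  expect_equal(names(which.max(med)), "high/high")
  lr <- logrank_test(sv$time_months, sv$event, grp)
  expect_equal(lr$df, 3)
  expect_lt(lr$p, 0.01)
})

test_that("rank and contingency tests match their oracles", {
  # identical samples: null result
  x <- c(1, 2, 3, 4)
  expect_equal(wilcoxon_test(x, x)$p, 1, tolerance = 0.05)
  expect_equal(wilcoxon_test(rep(2, 4), rep(2, 4))$statistic, 0)
  expect_equal(wilcoxon_test(x, x + 0, paired = TRUE)$p, 1)

  # exact small-sample Wilcoxon p equals full enumeration
  set.seed(12)
  xs <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  ys <- c(2.9, 6.3, 5.8, 7.7, 4.9, 8.1)
  w_obs <- sum(rank(c(xs, ys))[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  pool <- c(xs, ys)
  combos <- combn(12, 6)
  w_all <- apply(combos, 2, function(idx) {
    sum(rank(pool)[idx]) - 21
  })
  p_exact <- mean(abs(w_all - 18) >= abs(w_obs - 18)) # centre n*m/2 = 18
  expect_equal(wilcoxon_test(xs, ys)$p, p_exact, tolerance = 1e-10)

  # Kruskal-Wallis: all tied gives zero statistic, p = 1
  kw0 <- kruskal_wallis(rep(5, 9), rep(1:3, 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  kw <- kruskal_wallis(c(1, 5, 2, 8, 9, 4), rep(1:2, each = 3))
  expect_equal(kw$df, 1)
  expect_true(kw$p >= 0 && kw$p <= 1)

  # chi-square on the hand table (10,20 / 20,10) = 20/3
  cs <- chi_square(matrix(c(10, 20, 20, 10), 2))
  expect_equal(cs$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(cs$df, 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # a constant adjusted vector is a fixed point of the step-up
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "tmectx_spec_error")
})

test_that("mock subtraction floors at zero and passes range checks", {
  expect_equal(mock_subtract(2.0, 0.5), 1.5)
  expect_equal(mock_subtract(0.3, 0.5), 0)
  expect_equal(mock_subtract(c(4, 7), c(0, 0)), c(4, 7))
  expect_error(mock_subtract(101, 1), class = "tmectx_spec_error")
})

test_that("long-term survivor split handles censoring before the cutoff", {
  time <- c(30, 10, 10, 24)
  event <- c(0, 1, 0, 1)
  lab <- long_term_survivor(time, event, cutoff = 24)
  expect_equal(lab, c("long", "short", NA, "long"))
})
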