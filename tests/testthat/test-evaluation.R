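test_that("Kaplan-Meier matches hand product-limit on the three fixtures", {
  # 4 deaths, no censoring
  cv <- km_estimate(make_surv(1:4))
  expect_equal(cv$survival, c(0.75, 0.5, 0.25, 0))
  # all censored: curve stays at 1
  cv2 <- km_estimate(make_surv(c(2, 5, 9), event = c(0, 0, 0)))
  expect_true(all(cv2$survival == 1))
  expect_true(all(cv2$n_event == 0))
  # death at 1, censoring at 2, death at 3: S(1)=2/3, S(3)=0
  cv3 <- km_estimate(make_surv(c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(cv3$survival[cv3$time == 1], 2 / 3)
  expect_equal(cv3$survival[cv3$time == 3], 0)
  expect_equal(cv3$survival[cv3$time == 2], 2 / 3)  # censoring: no step
  expect_error(km_estimate(make_surv(numeric(0))), "")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(41)
  t <- round(rexp(40, 1 / 200)) + 1
  cv <- km_estimate(make_surv(t))
  emp <- vapply(cv$time, function(u) mean(t > u), numeric(1))
  expect_equal(cv$survival, emp, tolerance = 1e-12)
})

test_that("log-rank basics: null identity, relabeling, error cases", {
  surv <- make_surv(c(1, 2, 3, 4, 1, 2, 3, 4),
                    event = c(1, 0, 1, 0, 1, 0, 1, 0))
  g <- rep(c("a", "b"), each = 4)
  res <- logrank_test(surv, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  g2 <- rep(c("b", "a"), each = 4)
  expect_equal(logrank_test(surv, g2)$statistic, res$statistic)
  expect_error(logrank_test(surv, rep("a", 8)), "2 non-empty groups")
  none <- surv; none$event <- 0L
  expect_error(logrank_test(none, g), "no events")
})

test_that("log-rank p is within Monte-Carlo error of a permutation oracle", {
  set.seed(33)
  time <- c(rexp(15, 1 / 100), rexp(15, 1 / 260))
  event <- rbinom(30, 1, 0.8)
  g <- rep(c("a", "b"), each = 15)
  surv <- make_surv(time, event)
  obs <- logrank_test(surv, g)
  stat_obs <- logrank_stat_oracle(time, event, g)
  expect_equal(obs$statistic, stat_obs, tolerance = 1e-10)
  n_perm <- 2000  # the full 20,000-permutation check runs in acceptance
  perm_stats <- replicate(n_perm,
    logrank_stat_oracle(time, event, sample(g)))
  p_perm <- mean(perm_stats >= stat_obs - 1e-12)
  se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(obs$p - p_perm), 3 * se + 0.005)
})

test_that("three-group log-rank has two degrees of freedom and detects shift", {
  set.seed(52)
  time <- c(rexp(30, 1 / 50), rexp(30, 1 / 150), rexp(30, 1 / 450))
  surv <- make_surv(time, ids = sprintf("Q%03d", 1:90))
  res <- logrank_test(surv, rep(c("x", "y", "z"), each = 30))
  expect_equal(res$df, 2)
  expect_lt(res$p, 0.001)
})

test_that("age-stratified log-rank runs per stratum", {
  set.seed(61)
  n <- 80
  age <- sample(30:80, n, replace = TRUE)
  g <- rep(c("hi", "lo"), n / 2)
  time <- rexp(n, ifelse(g == "hi", 1 / 80, 1 / 300))
  surv <- make_surv(time, ids = sprintf("A%03d", 1:n), age = age)
  res <- age_stratified_logrank(surv, g, cutoff = 60)
  expect_named(res, c("younger", "older"))
  expect_lt(res$younger$p, 0.05)
})

test_that("chi-square/p conversion is an exact bijection", {
  # independent oracle: numerical inversion of the distribution function
  inv_oracle <- function(p, df)
    uniroot(function(q) pchisq(q, df, lower.tail = FALSE) - p,
            c(1e-8, 200), tol = 1e-12)$root
  expect_equal(chisq_p_conversion(p = 0.01, df = 1), inv_oracle(0.01, 1),
               tolerance = 1e-9)
  expect_equal(round(chisq_p_conversion(p = 0.01, df = 1)), 7)
  expect_equal(round(chisq_p_conversion(p = 1e-7, df = 1)), 28)
  expect_equal(chisq_p_conversion(p = 1e-7, df = 1), inv_oracle(1e-7, 1),
               tolerance = 1e-8)
  expect_equal(chisq_p_conversion(statistic = 0, df = 3), 1)
  for (df in 1:5) for (q in c(0.1, 1, 6.63, 28.37, 50)) {
    p <- chisq_p_conversion(statistic = q, df = df)
    expect_equal(chisq_p_conversion(p = p, df = df), q, tolerance = 1e-6 * q)
  }
  expect_error(chisq_p_conversion(p = 1.2), "")
  expect_error(chisq_p_conversion(p = 0.1, statistic = 2), "exactly one")
})

test_that("hypergeometric tail equals exhaustive enumeration", {
  # N=10, K=5, n=4, k=4: 5 favorable draws of C(10,4)=210
  expect_equal(hypergeometric_tail(4, K = 5, n = 4, N = 10), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeometric_tail(0, K = 5, n = 4, N = 10), 1)
  # enumeration oracle over a grid
  for (N in c(8, 12)) for (K in c(3, 5)) for (n in c(2, 4)) {
    pop <- c(rep(1, K), rep(0, N - K))
    draws <- combn(N, n)
    counts <- colSums(matrix(pop[draws], nrow = n))
    for (k in 0:min(K, n)) {
      expect_equal(hypergeometric_tail(k, K, n, N), mean(counts >= k),
                   tolerance = 1e-12)
      expect_equal(hypergeometric_tail(k, K, n, N, lower = TRUE),
                   mean(counts <= k), tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_tail(5, K = 4, n = 4, N = 10), "inconsistent")
})

test_that("p-value adjustment matches direct definitions", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(0.04, "benjamini-hochberg"), 0.04)
  # BH step-up oracle on random vectors
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(71)
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))^2
    expect_equal(adjust_pvalues(p, "benjamini-hochberg"), bh_oracle(p),
                 tolerance = 1e-12)
  }
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("risk cross-tabulation conserves margins and tests independence", {
  a <- setNames(factor(rep(c("low", "high"), each = 5)), paste0("P", 1:10))
  ct <- crosstab_risk(a, a)
  expect_equal(unname(diag(ct$table[1:2, 1:2])), c(5, 5))
  expect_equal(unname(ct$table["Sum", "Sum"]), 10)
  b <- setNames(factor(rep(c("low", "high"), 5)), paste0("P", 1:10))
  ct2 <- crosstab_risk(a, b)
  expect_equal(unname(ct2$table["Sum", "Sum"]), 10)
  expect_error(crosstab_risk(a, b[1:5]), "different sample sets")
  # chi-square statistic behaves like a null draw for random labels
  set.seed(81)
  stats <- replicate(200, {
    x <- factor(sample(c("l", "h"), 60, replace = TRUE))
    y <- factor(sample(c("l", "h"), 60, replace = TRUE))
    crosstab_risk(x, y)$chisq$statistic
  })
  expect_lt(mean(stats), qchisq(0.99, df = 1))
  expect_gte(mean(stats > qchisq(0.95, 1)), 0.005)
})

test_that("adjusted Rand index: identity, independence, formula check", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c(2, 3, 1)[a]
  expect_equal(adjusted_rand_index(a, perm), 1)  # label permutation
  set.seed(91)
  b <- sample(1:3, 30, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.35)
  # pair-counting oracle on a small case
  pair_oracle <- function(x, y) {
    n <- length(x)
    s_xy <- s_x <- s_y <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      s_x <- s_x + sx; s_y <- s_y + sy; s_xy <- s_xy + (sx && sy)
    }
    np <- choose(n, 2)
    exp_ <- s_x * s_y / np
    (s_xy - exp_) / ((s_x + s_y) / 2 - exp_)
  }
  x <- c(1, 1, 2, 2, 3, 3, 1, 2)
  y <- c(1, 2, 2, 2, 3, 1, 1, 2)
  expect_equal(adjusted_rand_index(x, y), pair_oracle(x, y),
               tolerance = 1e-12)
})
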