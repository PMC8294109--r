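test_that("penalized Cox selects a strongly prognostic module", {
  hits <- 0
  for (seed in 1:10) {
    sim <- sim_eigengene_surv(n = 300, K = 10,
                              beta = c(1.5, rep(0, 9)), seed = seed)
    sel <- select_prognostic_modules(sim$eigengenes, sim$surv, seed = seed)
    if ("M1" %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("penalized Cox input contracts are enforced", {
  sim <- sim_eigengene_surv(n = 50, K = 3, beta = c(1, 0, 0), seed = 1)
  no_events <- sim$surv
  no_events$event <- 0L
  expect_error(select_prognostic_modules(sim$eigengenes, no_events),
               "events")
  flat <- sim$eigengenes
  flat$values[2, ] <- 3
  expect_error(select_prognostic_modules(flat, sim$surv), "degenerate")
  one_mod <- sim$eigengenes
  one_mod$values <- one_mod$values[1, , drop = FALSE]
  expect_error(select_prognostic_modules(one_mod, sim$surv), "2 modules")
})

test_that("duplicated prognostic eigengene: the signal is still captured", {
  sim <- sim_eigengene_surv(n = 300, K = 4, beta = c(1.5, 0, 0, 0), seed = 3)
  dup <- sim$eigengenes
  dup$values <- rbind(dup$values, M5 = dup$values["M1", ] +
                        rnorm(ncol(dup$values), sd = 1e-6))
  sel <- select_prognostic_modules(dup, sim$surv, seed = 3)
  expect_true(any(c("M1", "M5") %in% sel$selected))
})

test_that("AFT recovers planted coefficients and the uncensored OLS limit", {
  sim <- sim_eigengene_surv(n = 1000, K = 2, beta = c(1, -0.5), sigma = 0.3,
                            censoring = 0.2, seed = 2)
  model <- fit_aft_model(sim$eigengenes, sim$surv, family = "lognormal")
  expect_lt(abs(model$coefficients$beta[["M1"]] - 1), 0.1)
  expect_lt(abs(model$coefficients$beta[["M2"]] - (-0.5)), 0.1)
  # uncensored log-normal AFT = least squares on log time (closed form)
  sim0 <- sim_eigengene_surv(n = 400, K = 2, beta = c(1, -0.5), sigma = 0.3,
                             censoring = 0, seed = 5)
  m0 <- fit_aft_model(sim0$eigengenes, sim0$surv, family = "lognormal")
  ols <- lm(log(sim0$surv$time) ~ t(sim0$eigengenes$values))
  expect_equal(m0$coefficients$mu, unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(m0$coefficients$beta), unname(coef(ols)[-1]),
               tolerance = 1e-6)
})

test_that("null coefficients stay within two standard errors mostly", {
  inside <- 0
  n_rep <- 100
  for (seed in 1:n_rep) {
    sim <- sim_eigengene_surv(n = 200, K = 2, beta = c(0, 0), seed = seed)
    df <- data.frame(t(sim$eigengenes$values), .time = sim$surv$time,
                     .event = sim$surv$event)
    fit <- survival::survreg(survival::Surv(.time, .event) ~ M1 + M2,
                             data = df, dist = "lognormal")
    se <- sqrt(diag(fit$var))[2]
    if (abs(coef(fit)[2]) <= 2 * se) inside <- inside + 1
  }
  expect_gte(inside / n_rep, 0.9)
})

test_that("predicted time follows the closed form and is monotone", {
  sim <- sim_eigengene_surv(n = 200, K = 2, beta = c(1, -0.5), seed = 4)
  model <- fit_aft_model(sim$eigengenes, sim$surv, family = "lognormal")
  eg0 <- sim$eigengenes
  eg0$values[] <- 0
  pred0 <- predict_survival_time(model, eg0)
  expect_equal(unname(pred0[1]),
               exp(model$coefficients$mu + model$coefficients$scale^2 / 2))
  # increasing a positive-coefficient eigengene increases predicted time
  up <- sim$eigengenes
  k <- names(which(model$coefficients$beta > 0))[1]
  up$values[k, ] <- up$values[k, ] + 1
  expect_true(all(predict_survival_time(model, up) >
                  predict_survival_time(model, sim$eigengenes)))
  expect_true(all(predict_survival_time(model, sim$eigengenes) > 0))
  missing_eg <- sim$eigengenes
  missing_eg$values <- missing_eg$values[-1, , drop = FALSE]
  expect_error(predict_survival_time(model, missing_eg), "lacks module")
  # training predictions track uncensored truth
  sim2 <- sim_eigengene_surv(n = 500, K = 2, beta = c(1, -0.5), sigma = 0.3,
                             censoring = 0, seed = 6)
  m2 <- fit_aft_model(sim2$eigengenes, sim2$surv)
  expect_gt(cor(predict_survival_time(m2, sim2$eigengenes), sim2$t_true),
            0.6)
})

test_that("three-way classification follows the cutpoint rules", {
  pred <- c(A = 1, B = 5, C = 10)
  rt <- classify_risk(pred, list(t_low = 2, t_high = 8))
  expect_identical(as.character(rt$risk_class),
                   c("high", "intermediate", "low"))
  # boundary values fall in the less extreme class
  rt2 <- classify_risk(c(A = 2, B = 8), list(t_low = 2, t_high = 8))
  expect_identical(as.character(rt2$risk_class),
                   c("intermediate", "intermediate"))
  rt3 <- classify_risk(c(A = 3, B = 3, C = 3), list(t_low = 3, t_high = 3))
  expect_true(all(rt3$risk_class == "intermediate"))
  expect_equal(sum(table(rt$risk_class)), 3)
})

test_that("risk classes order observed median survival", {
  sim <- sim_eigengene_surv(n = 600, K = 2, beta = c(1, -0.5), sigma = 0.3,
                            censoring = 0, seed = 8)
  model <- fit_aft_model(sim$eigengenes, sim$surv)
  risk <- classify_risk(predict_survival_time(model, sim$eigengenes),
                        model$cutpoints)
  med <- tapply(sim$surv$time[match(risk$sample_id, sim$surv$sample_id)],
                risk$risk_class, median)
  expect_true(med[["low"]] > med[["intermediate"]])
  expect_true(med[["intermediate"]] > med[["high"]])
})

test_that("quartile discretization follows the 25/50/25 printed rule", {
  cls <- discretize_quartile_risk(1:8)
  expect_identical(as.character(cls),
                   c("low", "low", "intermediate", "intermediate",
                     "intermediate", "intermediate", "high", "high"))
  expect_true(all(discretize_quartile_risk(rep(2, 6)) == "intermediate"))
  expect_error(discretize_quartile_risk(1:3), "at least 4")
  set.seed(30)
  props <- prop.table(table(discretize_quartile_risk(runif(1000))))
  expect_lt(abs(props[["low"]] - 0.25), 0.02)
  expect_lt(abs(props[["intermediate"]] - 0.5), 0.02)
  expect_lt(abs(props[["high"]] - 0.25), 0.02)
})

test_that("restratification restricts without reclassifying", {
  pred <- setNames(c(1, 3, 5, 7, 9), paste0("P", 1:5))
  rt <- classify_risk(pred, list(t_low = 2, t_high = 8))
  all_s <- restratify(rt, rt$sample_id)
  expect_equal(all_s$risk_table, rt)
  one <- restratify(rt, "P3")
  expect_equal(nrow(one$risk_table), 1)
  expect_identical(levels(one$high_vs_rest), c("high", "rest"))
  expect_error(restratify(rt, character(0)), "empty")
  expect_error(restratify(rt, "nope"), "absent")
})

test_that("risk model round-trips through JSON and scores new cohorts", {
  x <- rand_mat(12, 60, seed = 9)
  labels <- setNames(rep(1:2, each = 6), rownames(x))
  asg <- structure(list(gene_ids = rownames(x), labels = labels,
                        n_modules = 2L, params = list()),
                   class = "module_assignment")
  eg <- compute_eigengenes(x, asg)
  surv <- make_surv(exp(log(365) + eg$values["M1", ] +
                          0.3 * rnorm(60)), ids = colnames(x))
  model <- fit_aft_model(eg, surv)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$coefficients$beta, model$coefficients$beta)
  expect_equal(back$cutpoints$t_low, model$cutpoints$t_low)
  risk1 <- apply_risk_model(model, x)
  risk2 <- apply_risk_model(back, x)
  expect_equal(risk1, risk2)
})
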