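test_that("Kaplan-Meier equals empirical survival without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
})

test_that("Kaplan-Meier matches survfit on censored data", {
  skip_if_not_installed("survival")
  withr::with_seed(5, {
    t <- rexp(80, 0.05); u <- runif(80, 0, 30)
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  km <- km_estimate(time, ev)
  sf <- survival::survfit(survival::Surv(time, ev) ~ 1)
  expect_equal(km_survival_at(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches brute-force O-E computation", {
  # identical groups: no evidence
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # separated groups vs independent hand computation
  time <- c(1, 2, 3, 10, 11, 12); ev <- rep(1, 6)
  grp <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(time, ev, grp)
  oracle <- brute_logrank(time, ev, grp)
  expect_equal(lr$chisq, oracle$chisq, tolerance = 1e-10)
  expect_equal(lr$p, oracle$p, tolerance = 1e-10)
  # k identical groups: chisq 0, df k-1
  lrk <- logrank_test(rep(c(1, 2), 3), rep(1, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(lrk$df, 2)
  expect_lt(lrk$chisq, 1e-10)
})

test_that("log-rank agrees with survdiff on random censored data", {
  skip_if_not_installed("survival")
  withr::with_seed(21, {
    n <- 120
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.04 * exp(0.5 * g)); u <- runif(n, 0, 40)
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  lr <- logrank_test(time, ev, g)
  sd <- survival::survdiff(survival::Surv(time, ev) ~ g)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
})

test_that("Cox fit maximizes the partial likelihood", {
  # 6-subject binary covariate vs 1-D likelihood search
  x <- c(1, 0, 1, 1, 0, 0)
  time <- c(2, 4, 6, 8, 10, 12); ev <- c(1, 1, 1, 0, 1, 1)
  fit <- cox_fit(cbind(x = x), time, ev)
  b_star <- grid_search_cox(x, time, ev)
  expect_lt(abs(fit$coef[["x"]] - b_star), 1e-6)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-8)
  # duplicating every subject: invariance is exact under Breslow weights
  # and approximate under the Efron correction used here; the duplicated
  # fit must still agree with the reference implementation exactly
  fit2 <- cox_fit(cbind(x = rep(x, 2)), rep(time, 2), rep(ev, 2))
  expect_equal(fit2$coef, fit$coef, tolerance = 0.1)
  skip_if_not_installed("survival")
  cp2 <- survival::coxph(survival::Surv(rep(time, 2), rep(ev, 2)) ~ rep(x, 2),
                         ties = "efron")
  expect_equal(unname(fit2$coef), unname(coef(cp2)), tolerance = 1e-6)
})

test_that("Cox fit matches coxph with Efron ties", {
  skip_if_not_installed("survival")
  withr::with_seed(13, {
    n <- 150
    x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
    t <- ceiling(rexp(n, 0.03 * exp(0.7 * x1 - 0.3 * x2)))  # heavy monthly ties
    u <- ceiling(runif(n, 1, 60))
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  fit <- cox_fit(cbind(x1 = x1, x2 = x2), time, ev)
  cp <- survival::coxph(survival::Surv(time, ev) ~ x1 + x2, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(cp)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cp)))), tolerance = 1e-6)
  expect_equal(fit$loglik, cp$loglik[2], tolerance = 1e-8)
})

test_that("Cox fit is near zero under the null and flags separation", {
  withr::with_seed(31, {
    n <- 400
    x <- rnorm(n)
    time <- rexp(n, 0.05); ev <- rbinom(n, 1, 0.8)
  })
  fit <- cox_fit(cbind(x = x), time, ev)
  expect_lt(abs(fit$coef[["x"]]), 0.15)
  # perfect separation: monotone likelihood flagged
  xs <- c(1, 1, 1, 0, 0, 0)
  ts <- c(1, 2, 3, 10, 11, 12)
  expect_warning(sep <- cox_fit(cbind(x = xs), ts, rep(1, 6)),
                 "monotone|converge")
  expect_false(sep$converged)
  expect_lte(abs(sep$coef[["x"]]), 20)
  expect_error(cox_fit(cbind(x = rep(1, 6)), ts, rep(1, 6)), "constant")
})

test_that("concordance index matches exhaustive pair enumeration", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  withr::with_seed(8, {
    n <- 40
    risk <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.5 * risk)); u <- runif(n, 0, 15)
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  expect_equal(concordance_index(risk, time, ev),
               brute_cindex(risk, time, ev), tolerance = 1e-12)
})

test_that("cumulative/dynamic AUC equals Mann-Whitney AUC without censoring", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- 100 + 10 * rep
      m <- rnorm(n)
      t <- rexp(n, 0.03 * exp(0.3 * m))
      auc <- cumulative_dynamic_auc(m, t, rep(1, n), horizon = 30)$auc
      expect_lt(abs(auc - mw_auc(m, t, 30)), 1e-10)
    }
  })
})

test_that("binary-marker AUC equals (sensitivity + specificity) / 2", {
  withr::with_seed(19, {
    n <- 300
    mk <- rbinom(n, 1, 0.4)
    t <- rexp(n, 0.02 * exp(0.9 * mk))
  })
  sens <- mean(mk[t <= 60] == 1)
  spec <- mean(mk[t > 60] == 0)
  auc <- cumulative_dynamic_auc(mk, t, rep(1, n), 60)$auc
  expect_lt(abs(auc - (sens + spec) / 2), 1e-12)
})

test_that("AUC hits its boundaries and null in canonical cases", {
  withr::with_seed(23, {
    t <- rexp(200, 0.03)
    mk <- as.numeric(t <= 40)  # marks exactly the cases
    expect_equal(cumulative_dynamic_auc(mk, t, rep(1, 200), 40)$auc, 1)
    # independent marker: near 0.5 at large n
    m <- rnorm(2000); t2 <- rexp(2000, 0.03)
    expect_lt(abs(cumulative_dynamic_auc(m, t2, rep(1, 2000), 30)$auc - 0.5),
              0.05)
  })
  # no cases at horizon: missing
  out <- cumulative_dynamic_auc(rnorm(5), rep(100, 5), rep(1, 5), 10)
  expect_true(is.na(out$auc))
})

test_that("AUC is invariant to strictly monotone marker transforms", {
  withr::with_seed(29, {
    n <- 200
    mk <- rbinom(n, 1, 0.3)
    t <- rexp(n, 0.03 * exp(0.8 * mk)); u <- runif(n, 0, 80)
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  a_raw <- cumulative_dynamic_auc(mk, time, ev, 60)$auc
  # univariate Cox linear predictor of the call is a monotone transform
  b <- cox_fit(cbind(mk = mk), time, ev)$coef[["mk"]]
  a_lp <- cumulative_dynamic_auc(b * mk, time, ev, 60)$auc
  a_exp <- cumulative_dynamic_auc(exp(3 * mk + 2), time, ev, 60)$auc
  expect_equal(a_raw, a_lp, tolerance = 1e-12)
  expect_equal(a_raw, a_exp, tolerance = 1e-12)
})
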