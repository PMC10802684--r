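# Shared simulated dataset: one strong binary effect among noise features.
make_surv_data <- function(n = 300, p_noise = 8, beta = 1.1, seed = 101) {
  withr::with_seed(seed, {
    x_sig <- rbinom(n, 1, 0.4)
    X <- cbind(sig = x_sig,
               matrix(rbinom(n * p_noise, 1, 0.3), n,
                      dimnames = list(NULL, paste0("n", seq_len(p_noise)))))
    t <- rexp(n, 0.02 * exp(beta * x_sig))
    u <- runif(n, 0, 150)
    list(X = X, time = pmin(t, u), event = as.numeric(t <= u))
  })
}

test_that("penalized fit at penalty -> 0 matches the unpenalized Cox fit", {
  d <- make_surv_data(n = 400, p_noise = 2)
  f <- fit_penalized_cox(d$X, d$time, d$event, alpha = 1,
                         lambda = c(0.1, 0.01, 1e-7))
  b_pen <- coef(f, lambda = 1e-7)
  b_free <- cox_fit(d$X, d$time, d$event)$coef
  expect_equal(unname(b_pen), unname(b_free), tolerance = 1e-4)
})

test_that("a 1-covariate fit at penalty -> 0 matches a 1-D likelihood scan", {
  withr::with_seed(55, {
    n <- 200
    x <- rbinom(n, 1, 0.4)
    t <- rexp(n, 0.02 * exp(0.8 * x)) + runif(n, 0, 1e-4)  # untied
    u <- runif(n, 0, 120)
    time <- pmin(t, u); ev <- as.numeric(t <= u)
  })
  f <- fit_penalized_cox(matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                         time, ev, lambda = c(0.1, 1e-7))
  b_star <- grid_search_cox(x, time, ev)
  expect_lt(abs(coef(f, 1e-7)[["x"]] - b_star), 1e-4)
})

test_that("all coefficients vanish at and above the path maximum", {
  d <- make_surv_data()
  f <- fit_penalized_cox(d$X, d$time, d$event, alpha = 1)
  expect_equal(max(abs(coef(f, lambda = max(f$lambda)))), 0)
  expect_equal(max(abs(coef(f, lambda = 2 * max(f$lambda)))), 0)
})

test_that("fold assignment is a pure seeded function and event-stratified", {
  ids <- sprintf("s%03d", 1:100)
  ev <- rbinom(100, 1, 0.3)
  f1 <- cv_folds(ids, ev, k = 10, seed = 4)
  f2 <- cv_folds(ids, ev, k = 10, seed = 4)
  expect_identical(f1, f2)
  expect_false(identical(f1, cv_folds(ids, ev, k = 10, seed = 5)))
  # permuting sample order permutes folds consistently (function of ids)
  perm <- sample(100)
  f3 <- cv_folds(ids[perm], ev[perm], k = 10, seed = 4)
  expect_identical(f3, f1[perm])
  # every fold contains events
  expect_true(all(tapply(ev, f1, sum) > 0))
})

test_that("cross-validated selection finds the dominant feature, reproducibly", {
  d <- make_surv_data(n = 400, beta = 1.2)
  cv1 <- cv_select(d$X, d$time, d$event, alpha = 1, k = 10, seed = 7)
  cv2 <- cv_select(d$X, d$time, d$event, alpha = 1, k = 10, seed = 7)
  expect_identical(cv1$selected, cv2$selected)
  expect_true("sig" %in% cv1$selected$feature)
  # 1-SE rule: chosen penalty is never below the c-index maximizer
  expect_gte(cv1$lambda_1se, cv1$lambda_max)
})

test_that("pure-noise designs select nothing or nearly nothing", {
  hits <- vapply(1:5, function(s) {
    withr::with_seed(s + 200, {
      n <- 250
      X <- matrix(rbinom(n * 10, 1, 0.3), n,
                  dimnames = list(NULL, paste0("f", 1:10)))
      time <- rexp(n, 0.02); ev <- rbinom(n, 1, 0.75)
    })
    cv <- cv_select(X, time, ev, alpha = 1, k = 10, seed = s)
    nrow(cv$selected)
  }, 0)
  expect_gte(mean(hits <= 2), 0.8)
})

test_that("alpha search returns the grid element and breaks ties low", {
  d <- make_surv_data(n = 250, p_noise = 4)
  one <- alpha_search(d$X, d$time, d$event, alphas = 0.5, k = 5, seed = 3)
  expect_equal(one$best_alpha, 0.5)
  few <- alpha_search(d$X, d$time, d$event, alphas = c(0.2, 0.8), k = 5,
                      seed = 3)
  expect_true(few$best_alpha %in% c(0.2, 0.8))
  expect_equal(nrow(few$results), 2)
})

test_that("risk scores are invariant to feature rescaling", {
  d <- make_surv_data(n = 300, p_noise = 3)
  f1 <- fit_penalized_cox(d$X, d$time, d$event, alpha = 0.5)
  X2 <- d$X; X2[, "sig"] <- X2[, "sig"] * 100
  f2 <- fit_penalized_cox(X2, d$time, d$event, alpha = 0.5,
                          lambda = f1$lambda)
  r1 <- risk_score(f1, d$X, lambda = min(f1$lambda))
  r2 <- risk_score(f2, X2, lambda = min(f1$lambda))
  expect_equal(r1, r2, tolerance = 1e-3)
})

test_that("cross-validated AUC behaves at its extremes and under the null", {
  # a perfect feature gives CV-AUC 1 at the horizon
  withr::with_seed(71, {
    n <- 200
    t <- c(runif(n / 2, 1, 50), runif(n / 2, 70, 150))
    X <- cbind(perfect = rep(c(1, 0), each = n / 2),
               noise = rbinom(n, 1, 0.5))
  })
  out <- cv_auc(X, t, rep(1, n), alpha = 1, k = 5, seed = 2, horizon = 60,
                rule = "max")
  expect_equal(out$auc$auc, 1)
  # resubstitution AUC is at least the CV AUC on average
  deltas <- vapply(1:5, function(s) {
    d <- make_surv_data(n = 250, p_noise = 6, beta = 0.8, seed = 300 + s)
    cv <- cv_auc(d$X, d$time, d$event, alpha = 1, k = 5, seed = s,
                 rule = "max")
    fit <- fit_penalized_cox(d$X, d$time, d$event, alpha = 1)
    resub <- cumulative_dynamic_auc(
      risk_score(fit, d$X, lambda = cv$lambda), d$time, d$event, 60)$auc
    resub - cv$auc$auc
  }, 0)
  expect_gt(mean(deltas), 0)
})
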