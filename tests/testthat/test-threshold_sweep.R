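make_sweep_tbl <- function(feature, thresholds, auc) {
  out <- tibble::tibble(feature = feature, threshold = thresholds, auc = auc,
                        n_called = 10, n = 100)
  class(out) <- c("cnv_sweep", class(out))
  out
}

test_that("size-dependence rule follows max >= 0.6 with a <95% drop", {
  expect_true(size_dependence_flag(c(0.70, 0.66, 0.60)))
  expect_false(size_dependence_flag(rep(0.70, 5)))
  expect_false(size_dependence_flag(c(0.59, 0.50, 0.40)))
  expect_true(is.na(size_dependence_flag(c(0.7, NA, NA))))
  # the min is taken over non-missing entries only
  expect_true(size_dependence_flag(c(0.70, NA, 0.60)))
})

test_that("optimal threshold is the argmax with ties toward smaller", {
  sw <- make_sweep_tbl("f", seq(0.05, 0.5, 0.05),
                       c(0.5, 0.55, 0.6, 0.7, 0.6, 0.55, 0.5, 0.5, 0.5, 0.7))
  opt <- optimal_thresholds(sw)
  expect_equal(opt$threshold, 0.20)  # tie at 0.20 and 0.50 -> 0.20
  expect_equal(opt$auc, 0.7)
  sw2 <- make_sweep_tbl("g", c(0.05, 0.1), c(NA_real_, NA_real_))
  expect_message(opt2 <- optimal_thresholds(sw2), "omitting")
  expect_equal(nrow(opt2), 0)
})

test_that("a perfectly separating fraction gives AUC 1 at every threshold", {
  n <- 40
  t <- c(runif(n / 2, 1, 50), runif(n / 2, 70, 120))  # cases then controls
  fr <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                       fx = rep(c(1, 0), each = n / 2))
  sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                       time = t, event = 1)
  sw <- sweep_auc(fr, sv, "OS", horizon = 60)
  expect_true(all(abs(sw$auc - 1) < 1e-12))
})

test_that("fractions independent of outcome give null AUCs, unflagged", {
  withr::with_seed(41, {
    n <- 400
    fr <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         fx = rbeta(n, 2, 2))
    sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                         time = rexp(n, 0.02), event = 1)
  })
  sw <- sweep_auc(fr, sv, "OS")
  expect_true(all(abs(sw$auc - 0.5) < 0.12, na.rm = TRUE))
  s <- sweep_summary(sw)
  expect_false(isTRUE(s$size_dependent))
})

test_that("degenerate call vectors yield missing AUC", {
  fr <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                       fx = c(0.9, 0.95, 0.99, 1.0))
  sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                       time = c(10, 20, 70, 80), event = 1)
  sw <- sweep_auc(fr, sv, "OS", thresholds = c(0.05, 0.92))
  expect_true(is.na(sw$auc[sw$threshold == 0.05]))  # everyone called
  expect_false(is.na(sw$auc[sw$threshold == 0.92]))
})

test_that("sweep is deterministic on identical inputs", {
  sim <- simulate_cohort(sim_config(n = 80), seed = 2)
  fr <- arm_fractions(as_cohort(sim))
  s1 <- sweep_auc(fr, sim$survival, "OS")
  s2 <- sweep_auc(fr, sim$survival, "OS")
  expect_identical(s1, s2)
})

test_that("single-feature composite score reduces to the feature sweep", {
  withr::with_seed(43, {
    n <- 150
    fr <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         fx = rbeta(n, 2, 2))
    risky <- fr$fx >= 0.4
    t <- rexp(n, 0.02 * exp(log(3) * risky)); u <- runif(n, 0, 150)
    sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                         time = pmin(t, u), event = as.numeric(t <= u))
  })
  sw <- sweep_auc(fr, sv, "OS")
  cs <- composite_score_sweep(scoring_scheme(c(fx = 1)), fr, sv, "OS")
  expect_equal(cs$auc, sw$auc[sw$feature == "fx"], tolerance = 1e-12)
})

test_that("all-zero weights give a constant score and missing AUC", {
  fr <- tibble::tibble(sample_id = c("a", "b", "c"), fx = c(0.2, 0.5, 0.9))
  sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                       time = c(10, 50, 90), event = 1)
  cs <- composite_score_sweep(scoring_scheme(c(fx = 0)), fr, sv, "OS",
                              thresholds = 0.5)
  expect_true(is.na(cs$auc))
})

test_that("covariates enter the composite score and missing ones drop samples", {
  withr::with_seed(47, {
    n <- 120
    fr <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         fx = rbeta(n, 2, 2))
    grade <- rbinom(n, 2, 0.5)
    risky <- (fr$fx >= 0.4) + grade
    t <- rexp(n, 0.02 * exp(0.7 * risky))
    sv <- tibble::tibble(sample_id = fr$sample_id, endpoint = "OS",
                         time = t, event = 1)
    cov <- tibble::tibble(sample_id = fr$sample_id, grade = grade)
    cov$grade[1:5] <- NA
  })
  expect_message(
    cs <- composite_score_sweep(scoring_scheme(c(fx = 1),
                                               covariates = c(grade = 1)),
                                fr, sv, "OS", covariates = cov,
                                thresholds = c(0.2, 0.4, 0.6)),
    "dropped 5")
  expect_equal(unique(cs$n), 115)
  expect_true(all(cs$auc > 0.5))
})
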