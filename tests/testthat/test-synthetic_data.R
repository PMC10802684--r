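test_that("the generator is deterministic given (config, seed)", {
  cfg <- standard_scenarios()$single_threshold
  cfg$n <- 60
  s1 <- simulate_cohort(cfg, seed = 5)
  s2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$truth$fractions, s2$truth$fractions)
  s3 <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(s1$segments, s3$segments))
  # global RNG state is untouched
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, { invisible(simulate_cohort(cfg, seed = 5)); after <- runif(1) })
  expect_identical(before, after)
})

test_that("zero event probabilities give an alteration-free cohort", {
  cfg <- sim_config(n = 30, p_loss = 0, p_gain = 0)
  sim <- simulate_cohort(cfg, seed = 1)
  expect_true(all(as.matrix(sim$truth$fractions[-1]) == 0))
  fr <- arm_fractions(as_cohort(sim))
  calls <- binarize(fr, 0.05)
  expect_true(all(cnv_burden(calls)$burden == 0))
})

test_that("planted arms must exist in the arm table", {
  expect_error(
    sim_config(planted = tibble::tibble(arm_id = "99q", direction = "loss",
                                        threshold = 0.4, hr = 3)),
    "absent")
})

test_that("with no planted effect the true fractions carry no signal", {
  sim <- simulate_cohort(sim_config(n = 400), seed = 44)
  f <- as.matrix(sim$truth$fractions[-1])
  ci <- concordance_index(rowSums(f), sim$survival$time, sim$survival$event)
  expect_lt(abs(ci - 0.5), 0.06)
})

test_that("empirical censoring matches the analytic value", {
  cfg <- standard_scenarios()$single_threshold
  cfg$n <- 1000
  sim <- simulate_cohort(cfg, seed = 12)
  # analytic: P(T <= U) = 1 - (1 - exp(-lambda C)) / (lambda C) per sample
  lam <- cfg$baseline_rate * exp(sim$truth$linear_predictor)
  lc <- lam * cfg$censor_max
  analytic_event <- mean(1 - (1 - exp(-lc)) / lc)
  expect_lt(abs(mean(sim$survival$event) - analytic_event), 0.05)
})

test_that("the planted-arm carrier rate matches the Beta tail probability", {
  cfg <- standard_scenarios()$single_threshold
  cfg$n <- 1000
  sim <- simulate_cohort(cfg, seed = 13)
  f <- sim$truth$fractions$`1p_loss`
  carrier <- mean(f >= 0.4)
  # P(altered) * P(Beta(2,2) >= 0.4)
  analytic <- 0.5 * (1 - pbeta(0.4, 2, 2))
  expect_lt(abs(carrier - analytic), 0.03)
})

test_that("measured fractions recover the truth within grid resolution", {
  # low intensity noise isolates the grid pipeline from classification flips
  cfg <- sim_config(n = 40, p_loss = 0.4, p_gain = 0.3,
                    intensity = list(loss = c(-0.5, 0.01), gain = c(0.4, 0.01),
                                     neutral = c(0, 0.005)))
  sim <- simulate_cohort(cfg, seed = 9)
  fr <- arm_fractions(as_cohort(sim))
  truth <- sim$truth$fractions[match(fr$sample_id, sim$truth$fractions$sample_id), ]
  grid <- attr(fr, "grid")
  for (aid in grid$arm_id) {
    tol <- 2 / grid$n_grid[grid$arm_id == aid] + 1e-9
    for (dir in c("loss", "gain")) {
      fcol <- paste0(aid, "_", dir)
      expect_lt(max(abs(fr[[fcol]] - truth[[fcol]])), tol)
    }
  }
})

test_that("split-segment mode still recovers fractions (non-consecutive sum)", {
  cfg <- sim_config(n = 30, p_loss = 0.5, p_gain = 0.2, split_segments = TRUE,
                    intensity = list(loss = c(-0.5, 0.01), gain = c(0.4, 0.01),
                                     neutral = c(0, 0.005)))
  sim <- simulate_cohort(cfg, seed = 14)
  # two disjoint altered segments per arm event
  per_arm <- dplyr::count(
    dplyr::filter(sim$segments, .data$seg_mean < -0.1),
    .data$sample_id, .data$chrom)
  expect_gte(max(per_arm$n), 2)
  fr <- arm_fractions(as_cohort(sim))
  truth <- sim$truth$fractions[match(fr$sample_id, sim$truth$fractions$sample_id), ]
  grid <- attr(fr, "grid")
  for (aid in grid$arm_id) {
    tol <- 3 / grid$n_grid[grid$arm_id == aid] + 1e-9
    fcol <- paste0(aid, "_loss")
    expect_lt(max(abs(fr[[fcol]] - truth[[fcol]])), tol)
  }
})

test_that("scenario presets encode their planted structure", {
  sc <- standard_scenarios()
  expect_null(sc$null$planted)
  expect_equal(nrow(sc$single_threshold$planted), 1)
  expect_equal(sc$single_threshold$planted$threshold, 0.4)
  expect_equal(sc$single_threshold$planted$hr, 3)
  # pure interaction: no marginal terms, one joint term
  expect_null(sc$pair_interaction$planted)
  expect_equal(sc$pair_interaction$planted_pairs$hr, 3)
  expect_setequal(c(sc$early_late$schedule$early, sc$early_late$schedule$late),
                  c("1p", "2q", "3p", "6q", "1q", "4p", "5p", "6p"))
  expect_equal(sc$focal_spike$focal$end - sc$focal_spike$focal$start + 1, 3e5)
})

test_that("instability induces co-occurrence across arms", {
  cfg <- sim_config(n = 400, p_loss = 0.2, p_gain = 0, instability = TRUE)
  sim <- simulate_cohort(cfg, seed = 15)
  f <- as.matrix(sim$truth$fractions[-1])
  calls <- (f[, grepl("_loss", colnames(f))] > 0) * 1
  # positive association between arm events (driven by shared u)
  cors <- cor(calls)
  off_diag <- cors[upper.tri(cors)]
  expect_gt(mean(off_diag), 0.05)
})
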