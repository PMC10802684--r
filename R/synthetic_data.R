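#' Synthetic mini-genome arm table
#'
#' Six chromosomes with p and q arms of 3–10 Mb, separated by a small
#' centromeric gap — large enough for a few hundred 30-kb grid points per
#' arm, small enough that full-pipeline runs stay fast.
#'
#' @return An arm table tibble (chrom, arm, start, end, arm_id).
#' @export
synthetic_arms <- function() {
  tbl <- tibble::tribble(
    ~chrom, ~arm, ~start,      ~end,
    "1",    "p",  1,           8e6,
    "1",    "q",  8.5e6 + 1,   18e6,
    "2",    "p",  1,           6e6,
    "2",    "q",  6.5e6 + 1,   14e6,
    "3",    "p",  1,           5e6,
    "3",    "q",  5.5e6 + 1,   12e6,
    "4",    "p",  1,           4e6,
    "4",    "q",  4.5e6 + 1,   10e6,
    "5",    "p",  1,           3.5e6,
    "5",    "q",  4e6 + 1,     9e6,
    "6",    "p",  1,           3e6,
    "6",    "q",  3.5e6 + 1,   8e6
  )
  validate_arms(tbl)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model: per arm, an alteration event is drawn
#' (loss with probability `p_loss`, else gain with probability `p_gain`,
#' optionally scaled by a per-sample latent instability factor), its size
#' as a Beta-distributed fraction of the arm, and its placement as one
#' contiguous segment at a uniform offset (or two disjoint segments when
#' `split_segments`). Intensities are Gaussian around the loss/gain/neutral
#' levels. The hazard of the exponential event-time model multiplies the
#' baseline rate by `hr` for every planted arm whose true altered fraction
#' meets its threshold (and for every planted pair whose two members both
#' meet theirs); censoring is independent Uniform(0, `censor_max`).
#'
#' @param n Number of samples.
#' @param arms Arm table (default [synthetic_arms()]).
#' @param p_loss,p_gain Baseline per-arm event probabilities (scalar or
#'   named by `arm_id`).
#' @param frac_shape Beta shape parameters `c(shape1, shape2)` for the
#'   altered fraction (default Beta(2, 2)).
#' @param intensity List of `c(mean, sd)` for `loss`, `gain`, `neutral`.
#' @param planted Tibble (`arm_id`, `direction`, `threshold`, `hr`) of
#'   prognostic arms, or `NULL`.
#' @param planted_pairs Tibble (`arm_a`, `dir_a`, `threshold_a`, `arm_b`,
#'   `dir_b`, `threshold_b`, `hr`) of purely interacting pairs, or `NULL`.
#' @param baseline_rate Baseline hazard scale per month (default 0.02).
#' @param baseline_shape Weibull shape of the baseline hazard (default 1 =
#'   exponential, constant hazard; other values stress-test
#'   proportional-hazards assumptions downstream).
#' @param censor_max Upper bound of the uniform censoring time in months
#'   (default 150; with the default rates this yields roughly 30%
#'   censoring).
#' @param instability Draw a per-sample latent instability factor
#'   u ~ Uniform(0, 2) scaling all event probabilities (default `FALSE`).
#' @param schedule Optional list with `early` and `late` arm-id vectors;
#'   implies `instability`. Early arms get loss probability 0.4 + 0.15 u
#'   (prevalent at all instability levels); late arms get 0.18 u^2 (near 0
#'   at low instability, common at high).
#' @param focal Optional list (`arm_id`, `start`, `end`, `prob`): an extra
#'   focal loss segment over the given interval, added with probability
#'   `prob` to samples without an arm-level event on that arm.
#' @param split_segments Split each altered fraction across two disjoint
#'   segments to exercise non-consecutive summation (default `FALSE`).
#' @param endpoint Endpoint label for the emitted survival records
#'   (default `"OS"`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 500, arms = synthetic_arms(),
                       p_loss = 0.15, p_gain = 0.10,
                       frac_shape = c(2, 2),
                       intensity = list(loss = c(-0.5, 0.1),
                                        gain = c(0.4, 0.1),
                                        neutral = c(0, 0.03)),
                       planted = NULL, planted_pairs = NULL,
                       baseline_rate = 0.02, baseline_shape = 1,
                       censor_max = 150,
                       instability = FALSE, schedule = NULL, focal = NULL,
                       split_segments = FALSE, endpoint = "OS") {
  expand <- function(p) {
    if (length(p) == 1) setNames(rep(p, nrow(arms)), arms$arm_id)
    else p[arms$arm_id]
  }
  stopifnot(all(expand(p_loss) + expand(p_gain) <= 1),
            baseline_rate > 0, baseline_shape > 0, censor_max > 0)
  if (!is.null(planted)) {
    if (!all(planted$arm_id %in% arms$arm_id)) {
      abort("a planted arm is absent from the arm table")
    }
    stopifnot(all(planted$threshold > 0 & planted$threshold < 1),
              all(planted$hr > 0))
  }
  if (!is.null(schedule)) instability <- TRUE
  structure(list(n = n, arms = arms, p_loss = expand(p_loss),
                 p_gain = expand(p_gain), frac_shape = frac_shape,
                 intensity = intensity, planted = planted,
                 planted_pairs = planted_pairs,
                 baseline_rate = baseline_rate,
                 baseline_shape = baseline_shape, censor_max = censor_max,
                 instability = instability, schedule = schedule,
                 focal = focal, split_segments = split_segments,
                 endpoint = endpoint),
            class = "sim_config")
}

# Turn per-sample altered intervals on one arm into SEG rows (altered
# intervals plus neutral tiling of the remainder); fully vectorized.
# alt: tibble(sample_idx, start, end, class) with <=2 disjoint intervals
# per sample, sorted by (sample_idx, start).
arm_segment_rows <- function(alt, arm_start, arm_end, n) {
  rows_i <- integer(0); rows_s <- numeric(0); rows_e <- numeric(0)
  rows_c <- character(0)
  no_alt <- setdiff(seq_len(n), alt$sample_idx)
  if (length(no_alt) > 0) {
    rows_i <- c(rows_i, no_alt)
    rows_s <- c(rows_s, rep(arm_start, length(no_alt)))
    rows_e <- c(rows_e, rep(arm_end, length(no_alt)))
    rows_c <- c(rows_c, rep("neutral", length(no_alt)))
  }
  if (nrow(alt) > 0) {
    # altered intervals themselves
    rows_i <- c(rows_i, alt$sample_idx)
    rows_s <- c(rows_s, alt$start)
    rows_e <- c(rows_e, alt$end)
    rows_c <- c(rows_c, alt$class)
    # neutral gap before each interval: from previous interval end + 1
    # (or arm start) to interval start - 1
    first_of_sample <- !duplicated(alt$sample_idx)
    gap_start <- ifelse(first_of_sample, arm_start,
                        dplyr::lag(alt$end, default = 0) + 1)
    ok <- alt$start > gap_start
    rows_i <- c(rows_i, alt$sample_idx[ok])
    rows_s <- c(rows_s, gap_start[ok])
    rows_e <- c(rows_e, alt$start[ok] - 1)
    rows_c <- c(rows_c, rep("neutral", sum(ok)))
    # neutral tail after the last interval of each sample
    last_of_sample <- !duplicated(alt$sample_idx, fromLast = TRUE)
    ok <- last_of_sample & alt$end < arm_end
    rows_i <- c(rows_i, alt$sample_idx[ok])
    rows_s <- c(rows_s, alt$end[ok] + 1)
    rows_e <- c(rows_e, rep(arm_end, sum(ok)))
    rows_c <- c(rows_c, rep("neutral", sum(ok)))
  }
  tibble::tibble(sample_idx = rows_i, start = rows_s, end = rows_e,
                 class = rows_c)
}

#' Simulate a cohort with planted ground truth
#'
#' Draws per-arm alteration events, sizes and placements, emits a SEG-style
#' segment table and survival records whose hazard follows the planted
#' threshold effects, and returns the generative ground truth alongside.
#' Identical `(config, seed)` pairs yield identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; all randomness is local to the call.
#' @return A list of class `cnv_sim`: `segments`, `survival`, `truth`
#'   (list with `fractions`, `instability`, `linear_predictor`,
#'   `true_time`, `planted`, `planted_pairs`, `focal`), `config`.
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    n <- config$n
    arms <- config$arms
    ids <- sprintf("S%04d", seq_len(n))
    u <- if (config$instability) runif(n, 0, 2) else rep(1, n)
    fr <- config$frac_shape
    frac <- matrix(0, nrow = n, ncol = 2 * nrow(arms))
    colnames(frac) <- as.vector(t(outer(arms$arm_id, c("loss", "gain"),
                                        paste, sep = "_")))
    seg_parts <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      aid <- arms$arm_id[a]
      arm_start <- arms$start[a]; arm_end <- arms$end[a]
      arm_len <- arm_end - arm_start + 1
      pl <- rep(config$p_loss[aid], n)
      if (!is.null(config$schedule)) {
        if (aid %in% config$schedule$early) pl <- 0.4 + 0.15 * u
        else if (aid %in% config$schedule$late) pl <- 0.18 * u^2
      } else {
        pl <- pmin(1, pl * u)
      }
      pg <- pmin(1 - pl, config$p_gain[aid] * u)
      r <- runif(n)
      is_loss <- r < pl
      is_gain <- !is_loss & r < pl + pg
      has <- is_loss | is_gain
      f <- rbeta(n, fr[1], fr[2])
      dir <- ifelse(is_loss, "loss", "gain")
      if (any(has)) {
        frac[cbind(which(has), match(paste0(aid, "_", dir[has]),
                                     colnames(frac)))] <- f[has]
      }
      L <- pmax(1, round(f * arm_len))
      if (config$split_segments) {
        L1 <- floor(L / 2); L2 <- L - L1
        half <- floor(arm_len / 2)
        splittable <- has & L >= 4 & L1 < half & L2 < (arm_len - half)
        single <- has & !splittable
        s1 <- arm_start + floor(runif(n, 0, pmax(1, half - L1)))
        s2 <- arm_start + half + floor(runif(n, 0, pmax(1, arm_len - half - L2)))
        s0 <- arm_start + floor(runif(n, 0, arm_len - L + 1))
        alt <- dplyr::bind_rows(
          tibble::tibble(sample_idx = which(single), start = s0[single],
                         end = s0[single] + L[single] - 1,
                         class = dir[single]),
          tibble::tibble(sample_idx = which(splittable), start = s1[splittable],
                         end = s1[splittable] + L1[splittable] - 1,
                         class = dir[splittable]),
          tibble::tibble(sample_idx = which(splittable), start = s2[splittable],
                         end = s2[splittable] + L2[splittable] - 1,
                         class = dir[splittable]))
      } else {
        s0 <- arm_start + floor(runif(n, 0, arm_len - L + 1))
        alt <- tibble::tibble(sample_idx = which(has), start = s0[has],
                              end = s0[has] + L[has] - 1, class = dir[has])
      }
      if (!is.null(config$focal) && aid == config$focal$arm_id) {
        spike <- !has & runif(n) < config$focal$prob
        alt <- dplyr::bind_rows(
          alt,
          tibble::tibble(sample_idx = which(spike),
                         start = config$focal$start, end = config$focal$end,
                         class = "loss"))
      }
      alt <- alt[order(alt$sample_idx, alt$start), , drop = FALSE]
      rows <- arm_segment_rows(alt, arm_start, arm_end, n)
      rows$chrom <- arms$chrom[a]
      seg_parts[[a]] <- rows
    }
    seg <- dplyr::bind_rows(seg_parts)
    level_mean <- c(loss = config$intensity$loss[1],
                    gain = config$intensity$gain[1],
                    neutral = config$intensity$neutral[1])
    level_sd <- c(loss = config$intensity$loss[2],
                  gain = config$intensity$gain[2],
                  neutral = config$intensity$neutral[2])
    seg <- seg[order(seg$sample_idx, as.numeric(seg$chrom), seg$start), ,
               drop = FALSE]
    segments <- tibble::tibble(
      sample_id = ids[seg$sample_idx],
      chrom = seg$chrom,
      start = seg$start,
      end = seg$end,
      num_probes = pmax(1, round((seg$end - seg$start + 1) / 30000)),
      seg_mean = rnorm(nrow(seg), level_mean[seg$class], level_sd[seg$class]))

    lp <- rep(0, n)
    if (!is.null(config$planted)) {
      for (j in seq_len(nrow(config$planted))) {
        pj <- config$planted[j, ]
        fj <- frac[, paste0(pj$arm_id, "_", pj$direction)]
        lp <- lp + log(pj$hr) * (fj >= pj$threshold)
      }
    }
    if (!is.null(config$planted_pairs)) {
      for (j in seq_len(nrow(config$planted_pairs))) {
        pj <- config$planted_pairs[j, ]
        fa <- frac[, paste0(pj$arm_a, "_", pj$dir_a)]
        fb <- frac[, paste0(pj$arm_b, "_", pj$dir_b)]
        lp <- lp + log(pj$hr) * ((fa >= pj$threshold_a) & (fb >= pj$threshold_b))
      }
    }
    true_time <- (rexp(n, 1) /
                    (config$baseline_rate * exp(lp)))^(1 / config$baseline_shape)
    censor_time <- runif(n, 0, config$censor_max)
    survival <- tibble::tibble(
      sample_id = ids, endpoint = config$endpoint,
      time = pmin(true_time, censor_time),
      event = as.numeric(true_time <= censor_time))

    truth <- list(
      fractions = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                   tibble::as_tibble(frac)),
      instability = tibble::tibble(sample_id = ids, u = u),
      linear_predictor = lp, true_time = true_time,
      censor_time = censor_time,
      planted = config$planted, planted_pairs = config$planted_pairs,
      focal = config$focal, schedule = config$schedule)

    structure(list(segments = segments, survival = survival, truth = truth,
                   config = config, seed = seed),
              class = "cnv_sim")
  })
}

#' Build a `cnv_cohort` directly from a simulation
#' @param sim A `cnv_sim` from [simulate_cohort()].
#' @return A `cnv_cohort`.
#' @export
as_cohort <- function(sim) {
  stopifnot(inherits(sim, "cnv_sim"))
  build_cohort(sim$segments, sim$survival, sim$config$arms)
}

#' Named preset simulation scenarios
#'
#' * `single_threshold` — one planted loss arm (`1p`, threshold 0.4,
#'   HR 3, alteration probability 0.5), n = 500: the size-threshold
#'   recovery setting.
#' * `null` — no planted effects, n = 500: calibration of the
#'   size-dependence screen and model selection.
#' * `pair_interaction` — hazard increases (HR 3) only when `2p` and `5q`
#'   are co-lost beyond 40% of each arm; marginal HRs are 1.
#' * `early_late` — latent-instability schedule with four early arms
#'   (`1p`, `2q`, `3p`, `6q`) and four late arms (`1q`, `4p`, `5p`, `6p`);
#'   remaining arms are uncommon.
#' * `focal_spike` — a 300-kb loss interval on `3p` present in 25% of
#'   samples over a ~5% arm-level loss background, n = 200.
#'
#' @return Named list of [sim_config()] objects.
#' @export
standard_scenarios <- function() {
  arms <- synthetic_arms()
  base_p <- setNames(rep(0.15, nrow(arms)), arms$arm_id)
  planted_p <- base_p; planted_p["1p"] <- 0.5
  pair_p <- base_p; pair_p[c("2p", "5q")] <- 0.5
  uncommon_p <- setNames(rep(0.03, nrow(arms)), arms$arm_id)
  list(
    single_threshold = sim_config(
      n = 500, p_loss = planted_p, p_gain = 0.10,
      planted = tibble::tibble(arm_id = "1p", direction = "loss",
                               threshold = 0.4, hr = 3)),
    null = sim_config(n = 500, p_loss = base_p, p_gain = 0.10),
    pair_interaction = sim_config(
      n = 500, p_loss = pair_p, p_gain = 0.10,
      planted_pairs = tibble::tibble(arm_a = "2p", dir_a = "loss",
                                     threshold_a = 0.4,
                                     arm_b = "5q", dir_b = "loss",
                                     threshold_b = 0.4, hr = 3)),
    early_late = sim_config(
      n = 500, p_loss = uncommon_p, p_gain = 0.02,
      schedule = list(early = c("1p", "2q", "3p", "6q"),
                      late = c("1q", "4p", "5p", "6p"))),
    focal_spike = sim_config(
      n = 200, p_loss = 0.10, p_gain = 0.05,
      focal = list(arm_id = "3p", start = 2e6, end = 2.3e6 - 1, prob = 0.25))
  )
}
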