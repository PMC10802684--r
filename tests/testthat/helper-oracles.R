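# Independent oracles used across tests. These deliberately use brute-force
# or closed-form routes that do not share code with the package internals.

# Mann-Whitney AUC of cases (time <= h) vs controls (time > h); ties 0.5.
mw_auc <- function(marker, time, horizon) {
  cases <- marker[time <= horizon]
  ctrl <- marker[time > horizon]
  if (length(cases) == 0 || length(ctrl) == 0) return(NA_real_)
  mean(outer(cases, ctrl, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Explicit Cox partial log-likelihood (Breslow; exact for untied times),
# maximized by 1-D golden-section search.
grid_search_cox <- function(x, time, event, interval = c(-5, 5)) {
  pl <- function(b) {
    eta <- b * x
    sum(vapply(which(event == 1), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, 0))
  }
  stats::optimize(pl, interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Brute-force O-E log-rank for two groups.
brute_logrank <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Brute-force Harrell concordance by explicit pair enumeration.
brute_cindex <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
  }
  if (den == 0) NA_real_ else num / den
}

# Exact base-pair coverage fractions by interval arithmetic, for segment
# tables with non-overlapping segments on one arm.
interval_fractions <- function(segs, arm_start, arm_end) {
  cl <- ifelse(segs$seg_mean < -0.1, "loss",
               ifelse(segs$seg_mean > 0.15, "gain", "neutral"))
  s <- pmax(segs$start, arm_start); e <- pmin(segs$end, arm_end)
  keep <- s <= e
  bp <- e[keep] - s[keep] + 1
  tot <- sum(bp)
  c(loss = sum(bp[cl[keep] == "loss"]) / tot,
    gain = sum(bp[cl[keep] == "gain"]) / tot)
}

# Random grid-aligned segment table on a single arm: breakpoints at 30-kb
# boundaries, intensities drawn from the three class levels.
random_aligned_segments <- function(arm_start, arm_end, step = 30000,
                                    max_segs = 6) {
  n_pts <- floor((arm_end - arm_start) / step) + 1
  k <- sample(2:max_segs, 1)
  cutpts <- sort(sample(seq_len(n_pts - 1), min(k - 1, n_pts - 1)))
  bounds <- c(0, cutpts, n_pts)
  means <- sample(c(-0.5, 0, 0.4), length(bounds) - 1, replace = TRUE)
  tibble::tibble(
    sample_id = "s1",
    chrom = "1",
    start = arm_start + head(bounds, -1) * step,
    end = c(arm_start + cutpts * step - 1, arm_end),
    num_probes = 10,
    seg_mean = means)
}

# Tiny cohort builder from explicit per-sample segment specs.
make_cohort <- function(segments, time, event, arms = NULL,
                        endpoint = "OS") {
  arms <- arms %||% tibble::tibble(chrom = "1", arm = "p", start = 1,
                                   end = 3e6)
  ids <- unique(segments$sample_id)
  surv <- tibble::tibble(sample_id = ids, endpoint = endpoint,
                         time = time, event = event)
  build_cohort(segments, surv, arms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-sample segment rows covering an arm with given (start, end, mean).
seg_rows <- function(sid, chrom, starts, ends, means, probes = 10) {
  tibble::tibble(sample_id = sid, chrom = chrom, start = starts, end = ends,
                 num_probes = probes, seg_mean = means)
}
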