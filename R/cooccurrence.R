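pair_name <- function(a, b) paste(a, b, sep = "&")

#' Pairwise co-occurrence features from binary calls
#'
#' Builds one feature per unordered pair of input features, valued 1 when
#' both members are called in the sample (conjunction — a co-deletion or
#' co-gain), 0 otherwise; a missing member call propagates to a missing
#' pair. Co-occurrence modelling is limited to pairs; higher orders are
#' out of scope.
#'
#' @param calls A `cnv_calls` tibble at the chosen (optimal) thresholds.
#' @param feature_subset Features to pair (>= 2), e.g. the size-dependent
#'   features plus model-selected predictors.
#' @return A tibble (sample_id + one 0/1/NA column per pair named
#'   `"A&B"`), with the pair table in attribute `pairs`.
#' @export
pair_features <- function(calls, feature_subset = feature_columns(calls)) {
  feats <- intersect(feature_subset, feature_columns(calls))
  if (length(feats) < 2) abort("need at least two features to form pairs")
  m <- feature_matrix(calls)[, feats, drop = FALSE]
  combos <- utils::combn(feats, 2)
  pm <- matrix(NA_real_, nrow = nrow(m), ncol = ncol(combos))
  colnames(pm) <- pair_name(combos[1, ], combos[2, ])
  for (j in seq_len(ncol(combos))) {
    pm[, j] <- m[, combos[1, j]] * m[, combos[2, j]]
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = calls$sample_id),
                          tibble::as_tibble(pm))
  attr(out, "pairs") <- tibble::tibble(pair = colnames(pm),
                                       feature_a = combos[1, ],
                                       feature_b = combos[2, ])
  class(out) <- c("pair_calls", class(out))
  out
}

#' Co-occurrence summary statistics per feature pair
#'
#' For every unordered pair: joint and marginal counts, the Jaccard index,
#' and the odds ratio of the 2x2 table with the Haldane–Anscombe +0.5
#' correction applied when any cell is zero. The result doubles as an edge
#' list for network rendering.
#'
#' @inheritParams pair_features
#' @return A tibble: `feature_a`, `feature_b`, `n`, `n_a`, `n_b`, `n_both`,
#'   `jaccard`, `odds_ratio`.
#' @export
cooccurrence_summary <- function(calls, feature_subset = feature_columns(calls)) {
  feats <- intersect(feature_subset, feature_columns(calls))
  if (length(feats) < 2) abort("need at least two features to form pairs")
  m <- feature_matrix(calls)[, feats, drop = FALSE]
  combos <- utils::combn(feats, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    a <- m[, combos[1, j]]; b <- m[, combos[2, j]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    union <- n11 + n10 + n01
    or <- if (any(c(n11, n10, n01, n00) == 0)) {
      ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
    } else {
      (n11 * n00) / (n10 * n01)
    }
    tibble::tibble(feature_a = combos[1, j], feature_b = combos[2, j],
                   n = length(a), n_a = n11 + n10, n_b = n11 + n01,
                   n_both = n11,
                   jaccard = if (union == 0) 0 else n11 / union,
                   odds_ratio = or)
  })
}

#' Pair effect adjusted for total CNV burden
#'
#' Two-covariate Cox model of a co-occurrence indicator and the per-sample
#' CNV burden, testing whether the pair remains prognostic once the total
#' number of alterations is accounted for.
#'
#' @param pair_indicator 0/1 vector: both members of the pair called.
#' @param burden Integer CNV burden per sample ([cnv_burden()]).
#' @param time,event Survival outcome for the chosen endpoint.
#' @return A `cox_fit` with coefficients `pair` and `burden`; use
#'   [tidy()] for Wald tests.
#' @export
burden_adjusted_cox <- function(pair_indicator, burden, time, event) {
  ok <- !is.na(pair_indicator) & !is.na(burden)
  x <- cbind(pair = pair_indicator[ok], burden = burden[ok])
  if (max(x[, "pair"]) == min(x[, "pair"])) {
    abort("pair indicator is constant across samples")
  }
  if (max(x[, "burden"]) == min(x[, "burden"])) {
    abort("CNV burden is constant across samples")
  }
  cox_fit(x, time[ok], event[ok])
}

#' Four-group survival comparison for a CNV pair
#'
#' Splits samples into \{neither, A only, B only, both\}, estimates a
#' Kaplan–Meier curve per non-empty group, and reports the overall
#' log-rank test plus the pairwise "both vs A only" and "both vs B only"
#' contrasts (skipped with a warning when a group is empty).
#'
#' @param call_a,call_b 0/1 call vectors for the two features.
#' @param time,event Survival outcome.
#' @return An object of class `four_group_km`: `groups` (per-sample
#'   labels), `curves` (named list of `km_curve`), `overall`,
#'   `both_vs_a`, `both_vs_b` (each a `logrank_test` or `NULL`).
#' @export
four_group_km <- function(call_a, call_b, time, event) {
  ok <- !is.na(call_a) & !is.na(call_b) & is.finite(time)
  call_a <- call_a[ok]; call_b <- call_b[ok]
  time <- time[ok]; event <- event[ok]
  grp <- dplyr::case_when(
    call_a == 1 & call_b == 1 ~ "both",
    call_a == 1 ~ "A only",
    call_b == 1 ~ "B only",
    TRUE ~ "neither")
  grp <- factor(grp, levels = c("neither", "A only", "B only", "both"))
  present <- levels(grp)[table(grp) > 0]
  curves <- purrr::map(setNames(present, present), function(g) {
    km_estimate(time[grp == g], event[grp == g])
  })
  contrast <- function(g1, g2) {
    if (!all(c(g1, g2) %in% present)) {
      warn(paste0("four_group_km: group '", setdiff(c(g1, g2), present)[1],
                  "' is empty; contrast skipped"))
      return(NULL)
    }
    sel <- grp %in% c(g1, g2)
    logrank_test(time[sel], event[sel], droplevels(grp[sel]))
  }
  overall <- if (length(present) >= 2) {
    logrank_test(time, event, droplevels(grp))
  } else NULL
  structure(list(groups = grp, curves = curves, overall = overall,
                 both_vs_a = contrast("both", "A only"),
                 both_vs_b = contrast("both", "B only"),
                 n = table(grp)),
            class = "four_group_km")
}

#' @export
print.four_group_km <- function(x, ...) {
  cat("Four-group survival comparison (n):\n")
  print(x$n)
  if (!is.null(x$overall)) {
    cat("overall log-rank p = ", format(x$overall$p, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname four_group_km
#' @param object,x A `four_group_km`.
#' @param ... Ignored.
#' @method autoplot four_group_km
#' @export
autoplot.four_group_km <- function(object, ...) {
  df <- purrr::imap_dfr(object$curves, function(cv, g) {
    tibble::tibble(group = g, time = c(0, cv$time), surv = c(1, cv$surv))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL)
}
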