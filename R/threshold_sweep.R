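#' Default size-threshold grid: 5% to 95% by 5%
#' @return Numeric vector of thresholds.
#' @export
default_thresholds <- function() seq(0.05, 0.95, by = 0.05)

# Samples that inform the horizon ROC: events by the horizon (cases) or
# follow-up beyond it (controls). Censored before the horizon contribute
# to the KM weights but cannot make a degenerate call vector informative.
horizon_informative <- function(time, event, horizon) {
  (time <= horizon & event == 1) | time > horizon
}

#' AUC of every CNV feature across size thresholds
#'
#' For each feature and each threshold, binarizes the altered fraction and
#' computes the cumulative/dynamic AUC of the resulting 0/1 call at the
#' horizon. The AUC is missing when the call vector is constant among
#' horizon-informative samples (no ROC exists). Because the AUC is
#' invariant to monotone transforms of the marker, the AUC of the raw call
#' equals that of a univariate Cox linear predictor built on it.
#'
#' @param fractions An `arm_fractions` tibble.
#' @param survival Long survival records (`sample_id`, `endpoint`, `time`,
#'   `event`).
#' @param endpoint Endpoint label to evaluate (e.g. `"OS"`).
#' @param thresholds Size thresholds; default [default_thresholds()].
#' @param horizon AUC horizon in months; default 60.
#' @return A tibble of class `cnv_sweep` with columns `feature`,
#'   `threshold`, `auc`, `n_called`, `n`; attributes `endpoint`, `horizon`.
#' @export
sweep_auc <- function(fractions, survival, endpoint,
                      thresholds = default_thresholds(), horizon = 60) {
  sv <- survival[survival$endpoint == endpoint, , drop = FALSE]
  if (nrow(sv) == 0) abort(paste0("endpoint '", endpoint, "' not present"))
  sv <- sv[match(intersect(fractions$sample_id, sv$sample_id), sv$sample_id), ]
  frac <- feature_matrix(fractions)[sv$sample_id, , drop = FALSE]
  inform_idx <- horizon_informative(sv$time, sv$event, horizon)
  grid <- purrr::map_dfr(colnames(frac), function(f) {
    fv <- frac[, f]
    purrr::map_dfr(thresholds, function(th) {
      ok <- !is.na(fv)
      calls <- (fv[ok] >= th) * 1
      inf_calls <- calls[inform_idx[ok]]
      degenerate <- length(inf_calls) == 0 || min(inf_calls) == max(inf_calls)
      auc <- if (degenerate) NA_real_ else {
        cumulative_dynamic_auc(calls, sv$time[ok], sv$event[ok], horizon)$auc
      }
      tibble::tibble(feature = f, threshold = th, auc = auc,
                     n_called = sum(calls), n = sum(ok))
    })
  })
  attr(grid, "endpoint") <- endpoint
  attr(grid, "horizon") <- horizon
  class(grid) <- c("cnv_sweep", class(grid))
  grid
}

#' Flag a size-dependent AUC profile
#'
#' A feature is size-dependent when its maximum AUC across thresholds is at
#' least `min_auc` (default 0.60) and some other threshold falls below
#' `rel_drop` (default 95%) of that maximum — i.e. discrimination varies
#' materially with the size threshold. Missing AUCs are ignored; fewer than
#' two non-missing values yield `NA`.
#'
#' @param auc_profile Numeric vector of AUCs across thresholds.
#' @param min_auc Floor on the maximum AUC (default 0.60).
#' @param rel_drop Relative-drop cutoff (default 0.95).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
size_dependence_flag <- function(auc_profile, min_auc = 0.60, rel_drop = 0.95) {
  a <- auc_profile[!is.na(auc_profile)]
  if (length(a) < 2) return(NA)
  max(a) >= min_auc && min(a) < rel_drop * max(a)
}

#' Summarize a sweep: maxima, optimal thresholds and size-dependence flags
#'
#' The optimal threshold is the argmax of the AUC profile, ties broken
#' toward the smaller threshold. Features whose AUC is missing everywhere
#' are omitted with a message; features with fewer than two non-missing
#' AUCs carry an `NA` flag.
#'
#' @param sweep A `cnv_sweep` from [sweep_auc()].
#' @inheritParams size_dependence_flag
#' @return A tibble with one row per feature: `feature`, `opt_threshold`,
#'   `max_auc`, `min_auc`, `n_thresholds`, `size_dependent`.
#' @export
sweep_summary <- function(sweep, min_auc = 0.60, rel_drop = 0.95) {
  out <- sweep |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      opt_threshold = if (all(is.na(.data$auc))) NA_real_ else
        min(.data$threshold[!is.na(.data$auc) &
                              .data$auc == max(.data$auc, na.rm = TRUE)]),
      max_auc = if (all(is.na(.data$auc))) NA_real_ else max(.data$auc, na.rm = TRUE),
      min_auc = if (all(is.na(.data$auc))) NA_real_ else min(.data$auc, na.rm = TRUE),
      n_thresholds = sum(!is.na(.data$auc)),
      size_dependent = size_dependence_flag(.data$auc, !!min_auc, rel_drop),
      .groups = "drop"
    )
  omitted <- out$feature[is.na(out$opt_threshold)]
  if (length(omitted) > 0) {
    inform(paste0("sweep_summary: omitting ", length(omitted),
                  " feature(s) with no evaluable threshold"))
    out <- out[!is.na(out$opt_threshold), , drop = FALSE]
  }
  out
}

#' Optimal size threshold per feature
#'
#' @param sweep A `cnv_sweep`.
#' @return A tibble `feature`, `threshold`, `auc` (the per-feature argmax,
#'   ties toward the smaller threshold); features with no evaluable AUC are
#'   omitted.
#' @export
optimal_thresholds <- function(sweep) {
  s <- sweep_summary(sweep)
  tibble::tibble(feature = s$feature, threshold = s$opt_threshold,
                 auc = s$max_auc)
}

#' Define a composite scoring scheme over CNV calls and covariates
#'
#' A container for published composite risk scores: a weighted sum of
#' binary arm-level calls, optionally plus weighted clinical covariates.
#'
#' @param features Named numeric vector of weights, or a tibble with
#'   columns `feature`, `weight`. At least one feature is required.
#' @param covariates Optional named numeric vector of covariate weights.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(features, covariates = NULL) {
  if (is.data.frame(features)) features <- setNames(features$weight, features$feature)
  if (length(features) == 0) abort("a scoring scheme needs at least one CNV feature")
  structure(list(features = features, covariates = covariates),
            class = "scoring_scheme")
}

#' Sweep a composite score across uniform size thresholds
#'
#' At each uniform threshold, every scheme feature is binarized at that
#' threshold, samples are scored by the weighted sum of calls (plus any
#' clinical covariates), and the cumulative/dynamic AUC of the score is
#' computed at the horizon. Samples missing a covariate or a fraction are
#' dropped with a message; a constant score yields a missing AUC.
#'
#' @param scheme A [scoring_scheme()].
#' @param fractions An `arm_fractions` tibble containing every scheme
#'   feature.
#' @param survival,endpoint,thresholds,horizon As in [sweep_auc()].
#' @param covariates Optional tibble (`sample_id` + one column per named
#'   covariate in the scheme).
#' @return A tibble `threshold`, `auc`, `n`.
#' @export
composite_score_sweep <- function(scheme, fractions, survival, endpoint,
                                  covariates = NULL,
                                  thresholds = default_thresholds(),
                                  horizon = 60) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  feats <- names(scheme$features)
  missing_feats <- setdiff(feats, feature_columns(fractions))
  if (length(missing_feats) > 0) {
    abort(paste0("scheme feature(s) absent from fractions: ",
                 paste(missing_feats, collapse = ", ")))
  }
  sv <- survival[survival$endpoint == endpoint, , drop = FALSE]
  ids <- intersect(fractions$sample_id, sv$sample_id)
  cov_part <- 0
  if (!is.null(scheme$covariates)) {
    if (is.null(covariates)) abort("scheme names covariates but none supplied")
    cov_use <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
    cm <- as.matrix(cov_use[names(scheme$covariates)])
    complete <- stats::complete.cases(cm)
    if (any(!complete)) {
      inform(paste0("composite_score_sweep: dropped ", sum(!complete),
                    " sample(s) with missing covariates"))
    }
    ids <- ids[complete]
    cov_part <- drop(cm[complete, , drop = FALSE] %*% scheme$covariates)
  }
  sv <- sv[match(ids, sv$sample_id), ]
  frac <- feature_matrix(fractions)[ids, feats, drop = FALSE]
  complete_frac <- stats::complete.cases(frac)
  frac <- frac[complete_frac, , drop = FALSE]
  sv <- sv[complete_frac, ]
  if (length(cov_part) > 1) cov_part <- cov_part[complete_frac]
  inform_idx <- horizon_informative(sv$time, sv$event, horizon)
  purrr::map_dfr(thresholds, function(th) {
    score <- drop((frac >= th) %*% scheme$features) + cov_part
    s_inf <- score[inform_idx]
    degenerate <- length(s_inf) == 0 || min(s_inf) == max(s_inf)
    auc <- if (degenerate) NA_real_ else {
      cumulative_dynamic_auc(score, sv$time, sv$event, horizon)$auc
    }
    tibble::tibble(threshold = th, auc = auc, n = length(score))
  })
}

#' @rdname sweep_auc
#' @param object,x A `cnv_sweep`.
#' @param ... Ignored.
#' @method autoplot cnv_sweep
#' @export
autoplot.cnv_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$feature,
                                       fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey85") +
    ggplot2::labs(x = "Size threshold (fraction of arm)", y = NULL,
                  fill = paste0("AUC @ ", attr(object, "horizon"), " mo"))
}
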