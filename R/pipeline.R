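#' Run the full size-threshold analysis pipeline
#'
#' Orchestrates the stages end to end: cohort assembly (from a named
#' simulation scenario, a `cnv_sim`, or a prebuilt `cnv_cohort`), per-arm
#' altered fractions, the AUC threshold sweep with size-dependence
#' flagging and optimal-threshold selection, penalized Cox modelling at
#' the optimal thresholds with cross-validated AUC, pair co-occurrence
#' modelling over the prognostic pool, burden-binned prevalence clustering
#' with early/late labels, and focal-region detection on the flagged
#' arms. Each endpoint present in the survival records is analysed
#' independently. Stage outputs are pure functions of (inputs, config,
#' seed).
#'
#' @param input A scenario name from [standard_scenarios()], a `cnv_sim`,
#'   or a `cnv_cohort`.
#' @param endpoints Endpoints to analyse; default: all present.
#' @param horizon AUC horizon in months (default 60).
#' @param thresholds Size-threshold grid (default [default_thresholds()]).
#' @param alpha Elastic-net mixing parameter, or a numeric vector to
#'   search over (the best by CV c-index is used). Default 1 (lasso).
#' @param k CV folds (default 10).
#' @param seed Seed for simulation (when `input` is a scenario name) and
#'   fold assignment.
#' @param min_auc,rel_drop Size-dependence rule parameters.
#' @param cluster_k Number of feature clusters (default 3).
#' @param bin_min_n Minimum samples per integer burden bin (default 20).
#' @param focal_margin,focal_window,focal_flank Focal-detector parameters.
#' @param out_dir Optional directory: per-stage TSVs plus a JSON `report`
#'   are written there.
#' @return A list of class `cnv_report`: `config`, `package_version`,
#'   `cohort` summary, and one entry per endpoint with the stage results.
#' @export
run_pipeline <- function(input, endpoints = NULL, horizon = 60,
                         thresholds = default_thresholds(), alpha = 1,
                         k = 10, seed = 1, min_auc = 0.60, rel_drop = 0.95,
                         cluster_k = 3, bin_min_n = 20,
                         focal_margin = 0.05, focal_window = 5,
                         focal_flank = 3e6, out_dir = NULL) {
  config <- list(input = if (is.character(input)) input else class(input)[1],
                 horizon = horizon, thresholds = thresholds, alpha = alpha,
                 k = k, seed = seed, min_auc = min_auc, rel_drop = rel_drop,
                 cluster_k = cluster_k, bin_min_n = bin_min_n,
                 focal_margin = focal_margin, focal_window = focal_window,
                 focal_flank = focal_flank)
  cohort <- if (is.character(input)) {
    scen <- standard_scenarios()
    if (!input %in% names(scen)) {
      abort(paste0("unknown scenario '", input, "'; available: ",
                   paste(names(scen), collapse = ", ")))
    }
    as_cohort(simulate_cohort(scen[[input]], seed = seed))
  } else if (inherits(input, "cnv_sim")) {
    as_cohort(input)
  } else if (inherits(input, "cnv_cohort")) {
    input
  } else {
    abort("input must be a scenario name, a cnv_sim, or a cnv_cohort")
  }
  endpoints <- endpoints %||% unique(cohort$survival$endpoint)
  fractions <- arm_fractions(cohort)
  per_endpoint <- purrr::map(setNames(endpoints, endpoints), function(ep) {
    sweep <- sweep_auc(fractions, cohort$survival, ep,
                       thresholds = thresholds, horizon = horizon)
    summ <- sweep_summary(sweep, min_auc = min_auc, rel_drop = rel_drop)
    opt <- optimal_thresholds(sweep)
    calls <- binarize(fractions, opt)
    sv <- cohort$survival[cohort$survival$endpoint == ep, ]
    sv <- sv[match(calls$sample_id, sv$sample_id), ]

    model <- NULL; model_auc <- NULL
    usable <- vapply(feature_columns(calls), function(f) {
      v <- calls[[f]]
      length(unique(v[!is.na(v)])) > 1
    }, TRUE)
    if (sum(usable) >= 2) {
      X <- calls[c("sample_id", names(usable)[usable])]
      class(X) <- class(calls)
      best_alpha <- alpha
      if (length(alpha) > 1) {
        srch <- alpha_search(X, sv$time, sv$event, alphas = alpha, k = k,
                             seed = seed)
        best_alpha <- srch$best_alpha
      }
      model <- suppressWarnings(
        cv_select(X, sv$time, sv$event, alpha = best_alpha, k = k, seed = seed))
      model_auc <- suppressWarnings(
        cv_auc(X, sv$time, sv$event, alpha = best_alpha, k = k, seed = seed,
               horizon = horizon))
    }

    pool <- union(summ$feature[summ$size_dependent %in% TRUE],
                  if (!is.null(model)) model$selected$feature else character(0))
    pool <- setdiff(pool, NA)
    cooccur <- NULL
    if (length(pool) >= 2) {
      pairs <- pair_features(calls, pool)
      pair_usable <- vapply(feature_columns(pairs), function(f) {
        v <- pairs[[f]]
        length(unique(v[!is.na(v)])) > 1
      }, TRUE)
      pair_model <- NULL
      if (sum(pair_usable) >= 2) {
        PX <- pairs[c("sample_id", names(pair_usable)[pair_usable])]
        class(PX) <- class(pairs)
        pair_model <- suppressWarnings(
          cv_select(PX, sv$time, sv$event, alpha = 1, k = k, seed = seed))
      }
      cooccur <- list(pool = pool,
                      summary = cooccurrence_summary(calls, pool),
                      pair_model = pair_model)
    }

    burden <- cnv_burden(calls)
    bins <- burden_bins(burden, scheme = "integer", min_n = bin_min_n)
    clustering <- NULL; labels <- NULL
    if (nlevels(droplevels(bins$bin)) >= 2) {
      clustering <- prevalence_and_cluster(calls, bins, k = cluster_k)
      labels <- early_late_from_calls(calls, min_n = bin_min_n)
    }

    focal_arms <- unique(attr(fractions, "features")[
      attr(fractions, "features")$feature %in%
        summ$feature[summ$size_dependent %in% TRUE], c("arm_id", "direction")])
    focal <- purrr::pmap_dfr(focal_arms, function(arm_id, direction) {
      tr <- pileup(cohort, arm_id, direction)
      detect_focal(tr, window = focal_window, flank = focal_flank,
                   margin = focal_margin)
    })

    list(endpoint = ep, sweep = sweep, summary = summ,
         optimal_thresholds = opt, calls = calls, model = model,
         cv_auc = model_auc, cooccurrence = cooccur, burden = burden,
         bins = bins, clustering = clustering, early_late = labels,
         focal = focal)
  })
  report <- structure(list(
    config = config,
    package_version = as.character(utils::packageVersion("cnvsizer")),
    n_samples = length(cohort$samples),
    endpoints = per_endpoint), class = "cnv_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cnv_report <- function(x, ...) {
  cat("<cnv_report> ", x$n_samples, " samples, endpoints: ",
      paste(names(x$endpoints), collapse = ", "), "\n", sep = "")
  for (ep in names(x$endpoints)) {
    r <- x$endpoints[[ep]]
    sd_feats <- r$summary$feature[r$summary$size_dependent %in% TRUE]
    cat("  [", ep, "] size-dependent: ",
        if (length(sd_feats)) paste(sd_feats, collapse = ", ") else "none",
        "\n", sep = "")
    if (!is.null(r$model)) {
      cat("  [", ep, "] model selected: ",
          if (nrow(r$model$selected)) paste(r$model$selected$feature, collapse = ", ")
          else "none",
          "; CV-AUC = ",
          if (!is.null(r$cv_auc)) format(r$cv_auc$auc$auc, digits = 3) else "NA",
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes per-stage TSVs (sweep grid, summary, optimal thresholds, calls,
#' burden, prevalence, focal regions) and a machine-readable JSON
#' `report.json` embedding the resolved configuration and package version.
#'
#' @param report A `cnv_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(config = report$config, package_version = report$package_version,
             n_samples = report$n_samples, endpoints = list())
  for (ep in names(report$endpoints)) {
    r <- report$endpoints[[ep]]
    pre <- file.path(out_dir, paste0(ep, "_"))
    readr::write_tsv(r$sweep, paste0(pre, "sweep.tsv"), progress = FALSE)
    readr::write_tsv(r$summary, paste0(pre, "summary.tsv"), progress = FALSE)
    readr::write_tsv(r$calls, paste0(pre, "calls.tsv"), progress = FALSE)
    readr::write_tsv(r$burden, paste0(pre, "burden.tsv"), progress = FALSE)
    if (!is.null(r$clustering)) {
      readr::write_tsv(r$clustering$prevalence, paste0(pre, "prevalence.tsv"),
                       progress = FALSE)
    }
    if (nrow(r$focal) > 0) {
      readr::write_tsv(r$focal, paste0(pre, "focal.tsv"), progress = FALSE)
    }
    js$endpoints[[ep]] <- list(
      size_dependent = r$summary$feature[r$summary$size_dependent %in% TRUE],
      optimal_thresholds = r$optimal_thresholds,
      selected_features = if (!is.null(r$model)) r$model$selected else NULL,
      cv_cindex = if (!is.null(r$model)) r$model$cv_cindex else NULL,
      cv_auc = if (!is.null(r$cv_auc)) r$cv_auc$auc$auc else NULL,
      pair_selected = if (!is.null(r$cooccurrence$pair_model))
        r$cooccurrence$pair_model$selected else NULL,
      early_late = r$early_late,
      focal_regions = r$focal)
  }
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
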