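#' Per-sample CNV burden
#'
#' Total number of arm-level CNVs called per sample at the chosen (optimal)
#' thresholds; missing calls are excluded from the sum.
#'
#' @param calls A `cnv_calls` tibble.
#' @return A tibble `sample_id`, `burden`.
#' @export
cnv_burden <- function(calls) {
  m <- feature_matrix(calls)
  tibble::tibble(sample_id = calls$sample_id,
                 burden = unname(rowSums(m, na.rm = TRUE)))
}

#' Bin samples by CNV burden
#'
#' `scheme = "integer"` gives one bin per burden value, pooling the highest
#' values downward until every bin holds at least `min_n` samples (the
#' burden axis of a prevalence heatmap). `scheme = "quantile"` cuts the
#' burden distribution into `k` roughly equal groups.
#'
#' @param burden Tibble from [cnv_burden()] or a numeric vector.
#' @param scheme `"integer"` (default) or `"quantile"`.
#' @param min_n Minimum samples per bin for the integer scheme (default 20).
#' @param k Number of quantile bins (default 4).
#' @return A tibble `sample_id`, `burden`, `bin` (ordered factor). When
#'   the cohort is smaller than `min_n` a single bin is returned with a
#'   warning.
#' @export
burden_bins <- function(burden, scheme = c("integer", "quantile"),
                        min_n = 20, k = 4) {
  scheme <- match.arg(scheme)
  if (is.numeric(burden)) {
    burden <- tibble::tibble(sample_id = paste0("s", seq_along(burden)),
                             burden = burden)
  }
  b <- burden$burden
  if (length(b) < min_n && scheme == "integer") {
    warn("burden_bins: cohort smaller than min_n; using a single bin")
    burden$bin <- factor(rep("all", length(b)), ordered = TRUE)
    return(burden)
  }
  if (scheme == "quantile") {
    qs <- unique(quantile(b, probs = seq(0, 1, length.out = k + 1)))
    cutv <- cut(b, breaks = qs, include.lowest = TRUE, ordered_result = TRUE)
    burden$bin <- cutv
    return(burden)
  }
  vals <- sort(unique(b))
  counts <- vapply(vals, function(v) sum(b == v), 0)
  # pool from the top, then from the bottom, until every bin holds min_n
  groups <- as.list(vals)
  sizes <- counts
  while (length(groups) > 1 && sizes[length(sizes)] < min_n) {
    n <- length(groups)
    groups[[n - 1]] <- c(groups[[n - 1]], groups[[n]])
    sizes[n - 1] <- sizes[n - 1] + sizes[n]
    groups <- groups[-n]; sizes <- sizes[-n]
  }
  while (length(groups) > 1 && sizes[1] < min_n) {
    groups[[2]] <- c(groups[[1]], groups[[2]])
    sizes[2] <- sizes[1] + sizes[2]
    groups <- groups[-1]; sizes <- sizes[-1]
  }
  labels <- vapply(groups, function(g) {
    if (length(g) == 1) as.character(g[1])
    else if (max(g) == max(vals)) paste0(min(g), "+")
    else paste0(min(g), "-", max(g))
  }, "")
  assign_bin <- function(v) labels[which(vapply(groups, function(g) v %in% g, TRUE))[1]]
  burden$bin <- factor(vapply(b, assign_bin, ""), levels = labels, ordered = TRUE)
  burden
}

#' Per-bin CNV prevalence and hierarchical clustering of features
#'
#' Computes, for every CNV feature, the fraction of samples in each burden
#' bin carrying the call, then clusters features on their prevalence
#' profiles by Ward-linkage agglomerative clustering on Euclidean distance,
#' cut at `k` clusters. Features never called are assigned cluster 0
#' directly (the "uncommon" pool) and excluded from the tree.
#'
#' @param calls A `cnv_calls` tibble.
#' @param bins Output of [burden_bins()] for the same samples.
#' @param k Number of clusters to cut (default 3).
#' @param method Linkage method for [stats::hclust()] (default
#'   `"ward.D2"`).
#' @return A list of class `burden_clusters`: `prevalence` (tibble features
#'   x bins), `clusters` (tibble `feature`, `cluster`), `hclust`, `bins`.
#' @export
prevalence_and_cluster <- function(calls, bins, k = 3, method = "ward.D2") {
  bins <- bins[match(calls$sample_id, bins$sample_id), ]
  if (nlevels(droplevels(bins$bin)) < 2) abort("need at least two burden bins")
  m <- feature_matrix(calls)
  lv <- levels(droplevels(bins$bin))
  prev <- vapply(lv, function(bn) {
    rows <- which(bins$bin == bn)
    colMeans(m[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(m)))
  prev[is.nan(prev)] <- NA_real_
  never <- rowSums(prev > 0, na.rm = TRUE) == 0
  cl <- setNames(rep(0L, nrow(prev)), rownames(prev))
  hc <- NULL
  if (sum(!never) >= 2) {
    pm <- prev[!never, , drop = FALSE]
    pm[is.na(pm)] <- 0
    hc <- stats::hclust(stats::dist(pm), method = method)
    cl[!never] <- stats::cutree(hc, k = min(k, sum(!never)))
  } else {
    cl[!never] <- 1L
  }
  prev_tbl <- dplyr::bind_cols(tibble::tibble(feature = rownames(prev)),
                               tibble::as_tibble(prev))
  bin_n <- tibble::tibble(bin = lv,
                          n = vapply(lv, function(bn) sum(bins$bin == bn), 0))
  structure(list(prevalence = prev_tbl,
                 clusters = tibble::tibble(feature = names(cl),
                                           cluster = unname(cl)),
                 hclust = hc, bins = bin_n, k = k),
            class = "burden_clusters")
}

#' Classify CNVs as early, late or uncommon from prevalence profiles
#'
#' Formalizes the acquisition-order reading of a burden-binned prevalence
#' profile: a feature is `uncommon` when its prevalence never reaches
#' `floor` (default 0.10) in any bin; `late` when prevalence rises with
#' burden (Spearman correlation with bin rank at least `rho`, default 0.8)
#' and the lowest-burden bin sits below half the highest-burden bin; and
#' `early` otherwise (prevalent regardless of burden).
#'
#' @param prevalence The `prevalence` tibble from
#'   [prevalence_and_cluster()] (feature column + one column per ordered
#'   bin), or a `burden_clusters` object.
#' @param floor Prevalence floor for `uncommon` (default 0.10).
#' @param rho Spearman-correlation cutoff for `late` (default 0.8).
#' @return A tibble `feature`, `label`, `max_prev`, `trend_rho`.
#' @export
early_late_labels <- function(prevalence, floor = 0.10, rho = 0.8) {
  if (inherits(prevalence, "burden_clusters")) prevalence <- prevalence$prevalence
  pm <- as.matrix(prevalence[setdiff(names(prevalence), "feature")])
  if (ncol(pm) < 3) abort("early/late labelling needs at least three burden bins")
  purrr::map_dfr(seq_len(nrow(pm)), function(i) {
    dplyr::bind_cols(tibble::tibble(feature = prevalence$feature[i]),
                     classify_profile(pm[i, ], floor, rho))
  })
}

classify_profile <- function(p, floor, rho) {
  ok <- !is.na(p)
  mx <- if (any(ok)) max(p[ok]) else NA_real_
  trend <- if (sum(ok) >= 3 && sd(p[ok]) > 0) {
    suppressWarnings(cor(p[ok], seq_along(p)[ok], method = "spearman"))
  } else 0
  lab <- if (is.na(mx) || mx < floor) {
    "uncommon"
  } else if (trend >= rho && p[ok][1] < 0.5 * p[ok][sum(ok)]) {
    "late"
  } else {
    "early"
  }
  tibble::tibble(label = lab, max_prev = mx, trend_rho = trend)
}

#' Early/late labels with leave-one-out burden binning
#'
#' Applies the [early_late_labels()] rule to per-feature prevalence
#' profiles in which each feature's samples are binned by the burden of the
#' *other* features. Binning a feature against a burden that includes its
#' own call mechanically depresses its prevalence in low-burden bins (a
#' sample lacking the call is one step lower in burden), which masquerades
#' as a rising, "late" profile — severely so when the genome has few arms.
#' The leave-one-out bins remove that self-conditioning while preserving
#' the true association with overall instability.
#'
#' @param calls A `cnv_calls` tibble at the chosen thresholds.
#' @param min_n Minimum samples per integer burden bin (default 20).
#' @inheritParams early_late_labels
#' @return A tibble `feature`, `label`, `max_prev`, `trend_rho`.
#' @export
early_late_from_calls <- function(calls, min_n = 20, floor = 0.10,
                                  rho = 0.8) {
  m <- feature_matrix(calls)
  tot <- rowSums(m, na.rm = TRUE)
  purrr::map_dfr(colnames(m), function(f) {
    v <- m[, f]
    loo <- tot - ifelse(is.na(v), 0, v)
    bins <- suppressWarnings(burden_bins(loo, min_n = min_n))
    lv <- levels(droplevels(bins$bin))
    if (length(lv) < 3) {
      return(tibble::tibble(feature = f, label = NA_character_,
                            max_prev = NA_real_, trend_rho = NA_real_))
    }
    prev <- vapply(lv, function(bn) {
      mean(v[bins$bin == bn], na.rm = TRUE)
    }, 0)
    dplyr::bind_cols(tibble::tibble(feature = f),
                     classify_profile(prev, floor, rho))
  })
}

#' @rdname prevalence_and_cluster
#' @param object,x A `burden_clusters`.
#' @param ... Ignored.
#' @method autoplot burden_clusters
#' @export
autoplot.burden_clusters <- function(object, ...) {
  long <- tidyr::pivot_longer(object$prevalence, -"feature",
                              names_to = "bin", values_to = "prevalence")
  long$bin <- factor(long$bin, levels = object$bins$bin)
  ord <- if (!is.null(object$hclust)) {
    c(object$hclust$labels[object$hclust$order],
      setdiff(object$prevalence$feature, object$hclust$labels))
  } else object$prevalence$feature
  long$feature <- factor(long$feature, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$feature,
                                     fill = .data$prevalence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "CNV burden bin", y = NULL, fill = "Prevalence")
}
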