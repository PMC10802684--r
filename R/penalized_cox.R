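as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) {
      m <- feature_matrix(x)
    } else {
      m <- as.matrix(x)
    }
  } else {
    m <- as.matrix(x)
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (any(!is.finite(m))) abort("feature matrix contains non-finite values")
  m
}

# glmnet needs >= 2 columns; pad single-feature designs with an excluded
# zero column so the path for the real feature is unchanged.
pad_for_glmnet <- function(m) {
  if (ncol(m) >= 2) return(list(x = m, exclude = integer(0)))
  list(x = cbind(m, .pad = 0), exclude = 2L)
}

#' Elastic-net penalized Cox regression path
#'
#' Fits the regularization path of a Cox model under the elastic-net
#' penalty via `glmnet` coordinate descent. Features are standardized
#' internally; coefficients are reported on the original scale. The path
#' maximum is the smallest penalty at which every coefficient is zero.
#'
#' @param x Sample-by-feature matrix, data frame, or a `cnv_calls` /
#'   `arm_fractions` tibble.
#' @param time,event Survival outcome.
#' @param alpha Elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @param lambda Optional decreasing penalty sequence; by default a
#'   100-point log-spaced path computed from the data.
#' @param nlambda Path length when `lambda` is `NULL` (default 100).
#' @param thresh Coordinate-descent convergence threshold (default 1e-10,
#'   tight enough that near-zero penalties reproduce the unpenalized fit).
#' @return An object of class `penalized_cox`: the `glmnet` fit plus
#'   `alpha`, `lambda`, `features`.
#' @export
fit_penalized_cox <- function(x, time, event, alpha = 1, lambda = NULL,
                              nlambda = 100, thresh = 1e-10) {
  stopifnot(alpha >= 0, alpha <= 1)
  m <- as_feature_matrix(x)
  pad <- pad_for_glmnet(m)
  y <- cbind(time = time, status = event)
  fit <- glmnet::glmnet(pad$x, y, family = "cox", alpha = alpha,
                        lambda = lambda, nlambda = nlambda, thresh = thresh,
                        exclude = pad$exclude, standardize = TRUE)
  structure(list(glmnet = fit, alpha = alpha, lambda = fit$lambda,
                 features = colnames(m)),
            class = "penalized_cox")
}

#' Coefficients of a penalized Cox path at a penalty
#' @param object A `penalized_cox`.
#' @param lambda Penalty value (interpolated within the path).
#' @param ... Ignored.
#' @return Named numeric vector of coefficients (original feature scale).
#' @export
coef.penalized_cox <- function(object, lambda = min(object$lambda), ...) {
  b <- as.matrix(stats::coef(object$glmnet, s = lambda))
  setNames(b[object$features, 1], object$features)
}

#' Linear-predictor risk scores from a penalized Cox fit
#'
#' The risk metric is the product of the regression coefficients (fitted on
#' standardized features, reported on the original scale) and the feature
#' values, summed per sample — the Cox linear predictor. It is invariant to
#' feature rescaling.
#'
#' @param object A `penalized_cox`.
#' @param newdata Feature matrix/tibble with the fit's features.
#' @param lambda Penalty at which to extract coefficients.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(object, newdata, lambda = min(object$lambda)) {
  m <- as_feature_matrix(newdata)[, object$features, drop = FALSE]
  drop(m %*% coef(object, lambda = lambda))
}

#' @method tidy penalized_cox
#' @export
tidy.penalized_cox <- function(x, lambda = min(x$lambda), ...) {
  b <- coef(x, lambda = lambda)
  tibble::tibble(term = names(b), estimate = unname(b), lambda = lambda)
}

#' Event-stratified cross-validation folds
#'
#' Fold assignment is a pure function of `(seed, ids, event)`: ids are
#' sorted, balanced fold labels are permuted with the given seed within the
#' event and censored strata separately, so no fold is event-free unless
#' events are fewer than folds.
#'
#' @param ids Sample identifiers.
#' @param event Event indicators.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment aligned with `ids`.
#' @export
cv_folds <- function(ids, event, k = 10, seed = 1) {
  stopifnot(k >= 2, length(ids) == length(event))
  ord <- order(as.character(ids))
  fold <- integer(length(ids))
  withr::with_seed(seed, {
    for (s in sort(unique(event))) {
      idx <- ord[event[ord] == s]
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated penalty selection by c-index with the 1-SE rule
#'
#' Computes the per-penalty cross-validated Harrell c-index (mean and
#' standard error over event-stratified folds) along the full-data penalty
#' path, then chooses the largest penalty whose mean c-index is within one
#' standard error of the maximum — the sparsest model statistically
#' indistinguishable from the best.
#'
#' @inheritParams fit_penalized_cox
#' @param k Number of CV folds (default 10; reduced with a warning when
#'   `n/5 < k`).
#' @param seed Fold seed.
#' @return An object of class `cv_penalized_cox`: `curve` (tibble `lambda`,
#'   `mean_cindex`, `se_cindex`, `nonzero`), `lambda_max`, `lambda_1se`,
#'   `selected` (features with nonzero coefficients at `lambda_1se`),
#'   `cv_cindex` (mean at `lambda_1se`), `fit` (the full-data path),
#'   `alpha`, `k`, `seed`.
#' @export
cv_select <- function(x, time, event, alpha = 1, k = 10, seed = 1,
                      nlambda = 100) {
  m <- as_feature_matrix(x)
  n <- nrow(m)
  if (k > n / 5) {
    k <- max(2L, floor(n / 5))
    warn(paste0("cv_select: too many folds for n; using k = ", k))
  }
  full <- fit_penalized_cox(m, time, event, alpha = alpha, nlambda = nlambda)
  path <- full$lambda
  fold <- cv_folds(rownames(m), event, k = k, seed = seed)
  cmat <- matrix(NA_real_, nrow = k, ncol = length(path))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit_f <- tryCatch(
      fit_penalized_cox(m[tr, , drop = FALSE], time[tr], event[tr],
                        alpha = alpha, lambda = path),
      error = function(e) NULL)
    if (is.null(fit_f)) next
    pad <- pad_for_glmnet(m[!tr, , drop = FALSE])
    eta <- as.matrix(stats::predict(fit_f$glmnet, newx = pad$x, s = path,
                                     type = "link"))
    for (l in seq_along(path)) {
      cmat[f, l] <- concordance_index(eta[, l], time[!tr], event[!tr])
    }
  }
  mean_c <- apply(cmat, 2, mean, na.rm = TRUE)
  n_ok <- apply(cmat, 2, function(v) sum(!is.na(v)))
  se_c <- apply(cmat, 2, sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1))
  # Where the full-data model is empty its prediction is a constant score,
  # whose concordance is exactly 1/2 by the tie convention. Fold refits at
  # those penalties measure an artifact instead: a fold's own path maximum
  # exceeds the shared one precisely when the held-out fold is
  # anti-associated with the train-dominant feature, biasing the head of
  # the curve below 0.5. Use the definitional value there.
  nz_full <- colSums(as.matrix(
    stats::coef(full$glmnet, s = path))[full$features, , drop = FALSE] != 0)
  mean_c[nz_full == 0] <- 0.5
  se_c[nz_full == 0] <- 0
  imax <- which.max(mean_c)
  cutoff <- mean_c[imax] - se_c[imax]
  i1se <- min(which(mean_c >= cutoff))   # path is decreasing: min index = largest penalty
  b <- coef(full, lambda = path[i1se])
  curve <- tibble::tibble(lambda = path, mean_cindex = mean_c,
                          se_cindex = se_c, nonzero = nz_full)
  structure(list(curve = curve, lambda_max = path[imax],
                 lambda_1se = path[i1se],
                 selected = tibble::tibble(feature = names(b)[b != 0],
                                           coef = unname(b[b != 0])),
                 cv_cindex = mean_c[i1se], cv_cindex_max = mean_c[imax],
                 fit = full, alpha = alpha, k = k, seed = seed),
            class = "cv_penalized_cox")
}

#' @export
print.cv_penalized_cox <- function(x, ...) {
  cat("Cross-validated penalized Cox (alpha = ", x$alpha, ", ", x$k,
      "-fold)\n", "  lambda (1-SE) = ", format(x$lambda_1se, digits = 4),
      ", CV c-index = ", format(x$cv_cindex, digits = 4), ", ",
      nrow(x$selected), " feature(s) selected\n", sep = "")
  invisible(x)
}

#' @method tidy cv_penalized_cox
#' @export
tidy.cv_penalized_cox <- function(x, ...) x$curve

#' @method glance cv_penalized_cox
#' @export
glance.cv_penalized_cox <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, k = x$k, lambda_1se = x$lambda_1se,
                 lambda_max = x$lambda_max, cv_cindex = x$cv_cindex,
                 cv_cindex_max = x$cv_cindex_max, n_selected = nrow(x$selected))
}

#' Search the elastic-net mixing parameter over a grid
#'
#' Runs [cv_select()] at every alpha in the grid (same folds) and returns
#' the alpha whose 1-SE model attains the highest cross-validated c-index;
#' ties break toward the smaller alpha.
#'
#' @inheritParams cv_select
#' @param alphas Alpha grid; default 0.05 to 0.95 in steps of 0.05.
#' @return A list: `best_alpha`, `results` (tibble per alpha), `fits`
#'   (named list of `cv_penalized_cox`).
#' @export
alpha_search <- function(x, time, event, alphas = seq(0.05, 0.95, by = 0.05),
                         k = 10, seed = 1, nlambda = 100) {
  stopifnot(all(alphas > 0 & alphas <= 1))
  fits <- purrr::map(alphas, function(a) {
    suppressWarnings(cv_select(x, time, event, alpha = a, k = k, seed = seed,
                               nlambda = nlambda))
  })
  results <- purrr::map2_dfr(alphas, fits, function(a, f) {
    tibble::tibble(alpha = a, lambda_1se = f$lambda_1se,
                   cv_cindex = f$cv_cindex, n_selected = nrow(f$selected))
  })
  best <- results$alpha[which.max(results$cv_cindex)]   # which.max: first max = smallest alpha
  list(best_alpha = best, results = results,
       fits = setNames(fits, paste0("alpha_", alphas)))
}

#' Cross-validated time-dependent AUC of a penalized Cox model
#'
#' Refits the model on each training fold at a fixed penalty, pools the
#' out-of-fold linear predictors, and evaluates their cumulative/dynamic
#' AUC at the horizon — model performance without a held-out cohort.
#'
#' @inheritParams cv_select
#' @param horizon AUC horizon in months (default 60).
#' @param rule Which penalty to carry into the folds when `lambda` is
#'   `NULL`: `"1se"` (default, the selected model) or `"max"` (the
#'   c-index-maximizing penalty).
#' @param lambda Optional explicit penalty.
#' @return A list: `auc` (a `timedep_auc`), `lambda`, `scores` (tibble of
#'   pooled out-of-fold risk scores), `cv` (the `cv_penalized_cox` when one
#'   was computed).
#' @export
cv_auc <- function(x, time, event, alpha = 1, k = 10, seed = 1, horizon = 60,
                   rule = c("1se", "max"), lambda = NULL, nlambda = 100) {
  rule <- match.arg(rule)
  m <- as_feature_matrix(x)
  cv <- NULL
  if (is.null(lambda)) {
    cv <- cv_select(m, time, event, alpha = alpha, k = k, seed = seed,
                    nlambda = nlambda)
    lambda <- if (rule == "1se") cv$lambda_1se else cv$lambda_max
    k <- cv$k
  }
  fold <- cv_folds(rownames(m), event, k = k, seed = seed)
  eta <- rep(NA_real_, nrow(m))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit_f <- fit_penalized_cox(m[tr, , drop = FALSE], time[tr], event[tr],
                               alpha = alpha)
    eta[!tr] <- risk_score(fit_f, m[!tr, , drop = FALSE], lambda = lambda)
  }
  auc <- cumulative_dynamic_auc(eta, time, event, horizon = horizon)
  list(auc = auc, lambda = lambda,
       scores = tibble::tibble(sample_id = rownames(m), fold = fold,
                               risk = eta, time = time, event = event),
       cv = cv)
}
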