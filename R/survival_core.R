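#' Kaplan–Meier product-limit estimate
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A tibble of class `km_curve` with one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`. `surv` is the
#'   product-limit estimate just after `time`; S(0) = 1 implicitly.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  o <- order(time)
  ts <- time[o]; es <- event[o]
  ut <- unique(ts)
  idx <- findInterval(ts, ut)
  cnt <- tabulate(idx, nbins = length(ut))
  n_risk <- length(ts) - c(0, cumsum(cnt))[seq_along(ut)]
  n_event <- unname(drop(rowsum(es, idx)))
  n_censor <- cnt - n_event
  surv <- cumprod(1 - n_event / n_risk)
  structure(tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                           n_censor = n_censor, surv = surv),
            class = c("km_curve", class(tibble::tibble())))
}

#' Evaluate a Kaplan–Meier curve at arbitrary times
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Times at which to read off survival.
#' @return `S(t)` as a right-continuous step function; 1 before the first
#'   observed time.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Log-rank test for equality of survival across groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance, `df = #groups - 1`.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (>= 2 non-empty groups).
#' @return A list of class `logrank_test`: `chisq`, `df`, `p`,
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  k <- nlevels(group)
  if (k < 2) abort("log-rank test needs at least two non-empty groups")
  ut <- sort(unique(time[event == 1]))
  O <- E <- setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    if (n == 0 || d == 0) next
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g), 0)
    d_g <- vapply(levels(group), function(g) sum(time == t & event == 1 & group == g), 0)
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      w <- d * (n - d) / (n - 1)
      V <- V + w * (diag(n_g / n, k) - outer(n_g / n, n_g / n))
    }
  }
  i <- seq_len(k - 1)
  oe <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  chisq <- tryCatch(drop(t(oe) %*% solve(Vi, oe)), error = function(e) 0)
  if (!is.finite(chisq)) chisq <- 0
  p <- pchisq(chisq, df = k - 1, lower.tail = FALSE)
  structure(list(chisq = chisq, df = k - 1, p = p, observed = O, expected = E),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chisq = ", format(x$chisq, digits = 4), " on ", x$df,
      " df, p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

# Efron-tie partial log-likelihood, gradient and information for beta.
cox_loglik <- function(beta, x, time, event) {
  n <- nrow(x); p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  info <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1]))) {
    R <- time >= t
    D <- time == t & event == 1
    d <- sum(D)
    sR <- sum(w[R]); sD <- sum(w[D])
    xR <- colSums(x[R, , drop = FALSE] * w[R])
    xD <- colSums(x[D, , drop = FALSE] * w[D])
    xxR <- crossprod(x[R, , drop = FALSE] * sqrt(w[R]))
    xxD <- crossprod(x[D, , drop = FALSE] * sqrt(w[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      den <- sR - (l / d) * sD
      num <- xR - (l / d) * xD
      num2 <- xxR - (l / d) * xxD
      ll <- ll - log(den)
      grad <- grad - num / den
      info <- info + num2 / den - tcrossprod(num / den)
    }
    grad <- grad + colSums(x[D, , drop = FALSE])
  }
  list(loglik = ll, gradient = grad, information = info)
}

#' Cox proportional hazards fit by Newton–Raphson
#'
#' Maximizes the partial likelihood with the Efron correction for tied
#' event times. Convergence is declared when the maximum absolute gradient
#' falls below `tol`; monotone-likelihood divergence (perfect separation)
#' is capped at |beta| = 20 and flagged as non-converged.
#'
#' @param x Covariate matrix or data frame (n x p, no constant columns).
#' @param time,event Survival outcome as in [km_estimate()].
#' @param tol Gradient tolerance, default 1e-8.
#' @param max_iter Maximum Newton iterations, default 100.
#' @return An object of class `cox_fit`: `coef`, `se`, `loglik`,
#'   `loglik_null`, `gradient`, `converged`, `iter`, `n`, `n_event`.
#' @export
cox_fit <- function(x, time, event, tol = 1e-8, max_iter = 100) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & is.finite(time)
  x <- x[keep, , drop = FALSE]; time <- time[keep]; event <- event[keep]
  if (any(apply(x, 2, function(col) max(col) == min(col)))) {
    abort("cox_fit: a covariate is constant across samples")
  }
  p <- ncol(x)
  beta <- numeric(p)
  ll0 <- cox_loglik(numeric(p), x, time, event)$loglik
  fit <- cox_loglik(beta, x, time, event)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (max(abs(fit$gradient)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(fit$information, fit$gradient),
                     error = function(e) fit$gradient / (abs(diag(fit$information)) + 1e-8))
    new_beta <- beta + step
    # step-halving to guarantee ascent
    half <- 0
    new_fit <- cox_loglik(new_beta, x, time, event)
    while (new_fit$loglik < fit$loglik && half < 20) {
      step <- step / 2
      new_beta <- beta + step
      new_fit <- cox_loglik(new_beta, x, time, event)
      half <- half + 1
    }
    improved <- new_fit$loglik - fit$loglik
    beta <- new_beta
    fit <- new_fit
    # likelihood plateau at floating precision with a near-zero gradient:
    # converged for all practical purposes (coxph uses the same criterion)
    if (abs(improved) < 1e-11 * (abs(fit$loglik) + 1) &&
        max(abs(fit$gradient)) < 1e-5) {
      converged <- TRUE
      break
    }
    if (any(abs(beta) > 20)) {
      beta <- pmin(pmax(beta, -20), 20)
      fit <- cox_loglik(beta, x, time, event)
      warn("cox_fit: monotone likelihood, coefficient capped at |20|")
      break
    }
  }
  if (!converged && iter >= max_iter) {
    warn("cox_fit: Newton-Raphson did not converge")
  }
  se <- tryCatch(sqrt(diag(solve(fit$information))),
                 error = function(e) rep(NA_real_, p))
  structure(list(coef = setNames(drop(beta), colnames(x)),
                 se = setNames(se, colnames(x)),
                 loglik = fit$loglik, loglik_null = ll0,
                 gradient = fit$gradient, converged = converged, iter = iter,
                 n = length(time), n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties), n = ", x$n, ", events = ",
      x$n_event, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  z <- x$coef / x$se
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))),
                 hazard.ratio = unname(exp(x$coef)))
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n.event = x$n_event, logLik = x$loglik,
                 logLik.null = x$loglik_null,
                 statistic.lrt = 2 * (x$loglik - x$loglik_null),
                 converged = x$converged, iter = x$iter)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the sample with the higher risk score
#' has the earlier event; risk ties count 1/2. A pair is usable when the
#' shorter time ends in an event (or, for equal times, exactly one of the
#' two is an event).
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time,event Survival outcome.
#' @return Concordance in \[0, 1\], or `NA` if there are no usable pairs.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(all(is.finite(risk)))
  n <- length(risk)
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(event, n, n); ej <- t(ei)
  ri <- matrix(risk, n, n); rj <- t(ri)
  usable <- (ti < tj & ei == 1) | (ti == tj & ei == 1 & ej == 0)
  if (!any(usable)) return(NA_real_)
  conc <- (ri > rj) + 0.5 * (ri == rj)
  sum(conc[usable]) / sum(usable)
}

#' Cumulative/dynamic time-dependent AUC at a horizon
#'
#' Area under the time-dependent ROC curve at horizon `h`, with cases
#' defined cumulatively (event by `h`) and controls dynamically (event-free
#' beyond `h`). Sensitivity and specificity at each marker cutpoint are
#' estimated from Kaplan–Meier survival within the marker strata
#' (the Heagerty–Lumley–Pepe form); ties in the marker contribute 1/2.
#' Without censoring before the horizon this reduces exactly to the
#' Mann–Whitney AUC of cases versus controls.
#'
#' @param marker Numeric marker (higher = higher risk).
#' @param time,event Survival outcome.
#' @param horizon Evaluation time in the same units as `time`
#'   (default 60 months = 5 years).
#' @return A list of class `timedep_auc`: `auc` (or `NA` when there are no
#'   cases or no controls at the horizon), `horizon`, `n_cases`,
#'   `n_controls`.
#' @export
cumulative_dynamic_auc <- function(marker, time, event, horizon = 60) {
  ok <- is.finite(marker) & is.finite(time)
  marker <- marker[ok]; time <- time[ok]; event <- event[ok]
  n_cases <- sum(time <= horizon & event == 1)
  n_controls <- sum(time > horizon)
  empty <- list(auc = NA_real_, horizon = horizon,
                n_cases = n_cases, n_controls = n_controls)
  class(empty) <- "timedep_auc"
  if (n_cases == 0 || n_controls == 0) return(empty)
  S_h <- km_survival_at(km_estimate(time, event), horizon)
  if (S_h <= 0 || S_h >= 1) return(empty)
  cuts <- sort(unique(marker))
  roc <- purrr::map_dfr(c(-Inf, cuts), function(cc) {
    hi <- marker > cc
    p_hi <- mean(hi)
    S_hi <- if (any(hi)) km_survival_at(km_estimate(time[hi], event[hi]), horizon) else 1
    S_lo <- if (any(!hi)) km_survival_at(km_estimate(time[!hi], event[!hi]), horizon) else 1
    tpr <- p_hi * (1 - S_hi) / (1 - S_h)
    fpr <- 1 - (1 - p_hi) * S_lo / S_h
    tibble::tibble(fpr = min(max(fpr, 0), 1), tpr = min(max(tpr, 0), 1))
  })
  # integrate along the cutpoint path (fpr decreasing in the cut order)
  auc <- sum(-diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(list(auc = auc, horizon = horizon, n_cases = n_cases,
                 n_controls = n_controls), class = "timedep_auc")
}

#' @export
print.timedep_auc <- function(x, ...) {
  cat("Cumulative/dynamic AUC at t = ", x$horizon, ": ",
      format(x$auc, digits = 4), " (", x$n_cases, " cases, ", x$n_controls,
      " controls)\n", sep = "")
  invisible(x)
}

#' @rdname km_estimate
#' @param object,x A `km_curve`.
#' @param ... Ignored.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble::tibble(time = c(0, object$time), surv = c(1, object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability")
}
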