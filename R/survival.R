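#' Dichotomize a biomarker at its median
#'
#' Values strictly above the across-sample median are `High`; values at or
#' below it are `Low`. The tie convention (median itself is `Low`) is
#' deterministic and guarantees `High` strictly exceeds the median.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return Factor with levels `Low` (reference) and `High`.
#' @export
#' @examples
#' median_dichotomize(c(1, 2, 2, 3))  # Low Low Low High
median_dichotomize <- function(values) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 2) stop("need at least 2 finite values")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite")
  }
  med <- median(values)
  if (all(values == values[1])) stop("all values identical: no median split")
  factor(ifelse(values > med, "High", "Low"), levels = c("Low", "High"))
}

.check_surv <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (anyNA(time) || any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive and finite")
  }
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  list(time = time, event = as.integer(event))
}

# Product-limit estimate for one group: rows at each distinct observed time.
.km_one <- function(time, event) {
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` per
#' group, with censored subjects remaining in the risk set until their
#' censoring time.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Optional grouping vector; `NULL` fits one curve.
#' @return Data frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (the estimate just after `time`).
#' @export
km_curve <- function(time, event, group = NULL) {
  s <- .check_surv(time, event)
  if (is.null(group)) group <- rep("all", length(s$time))
  group <- as.character(group)
  if (length(group) != length(s$time)) stop("group length mismatch")
  out <- lapply(sort(unique(group)), function(g) {
    sel <- group == g
    if (!any(sel)) stop("empty group: ", g)
    cbind(group = g, .km_one(s$time[sel], s$event[sel]))
  })
  do.call(rbind, out)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group 1 are compared
#' with their hypergeometric expectation given the risk sets; the statistic
#' is `(sum(O - E))^2 / sum(V)` referred to a 1-df chi-square distribution.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `df` (1), `p`, `observed`, `expected` (for
#'   the first group in sorted label order).
#' @export
logrank_test <- function(time, event, group) {
  s <- .check_surv(time, event)
  group <- as.character(group)
  labs <- sort(unique(group))
  if (length(labs) != 2) {
    stop("log-rank test requires exactly 2 groups, found ", length(labs))
  }
  if (any(!labs %in% group)) stop("empty group")
  if (sum(s$event) < 1) stop("at least one event is required")
  g1 <- group == labs[1]
  ev_times <- sort(unique(s$time[s$event == 1]))
  o <- e <- v <- 0
  for (t in ev_times) {
    at_risk <- s$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(s$time == t & s$event == 1)
    d1 <- sum(s$time == t & s$event == 1 & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v <= 0) {
    stat <- 0
    p <- 1
  } else {
    stat <- (o - e)^2 / v
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = 1L, p = p, observed = o, expected = e,
       groups = labs)
}

# Efron partial likelihood, score and information for design matrix x.
# Risk-set sums S0, S1, S2 are reverse cumulative sums over time-sorted
# subjects, so one evaluation is O(n p^2 + events p^2).
.efron_quants <- function(beta, time, event, x) {
  n <- nrow(x)
  p <- ncol(x)
  o <- order(time)
  ts <- time[o]
  ev <- event[o]
  xs <- x[o, , drop = FALSE]
  eta <- drop(xs %*% beta)
  w <- exp(eta)
  wx <- xs * w

  rev_cumsum <- function(v) rev(cumsum(rev(v)))
  rc0 <- rev_cumsum(w)
  rc1 <- apply(wx, 2, rev_cumsum)
  if (p == 1) rc1 <- matrix(rc1, ncol = 1)
  # outer-product rows w_i * x_i x_i^T flattened to p^2 columns
  xx <- xs[, rep(seq_len(p), times = p), drop = FALSE] *
    xs[, rep(seq_len(p), each = p), drop = FALSE]
  rc2 <- apply(xx * w, 2, rev_cumsum)
  if (n == 1) rc2 <- matrix(rc2, nrow = 1)

  is_ev <- ev == 1
  ut <- unique(ts[is_ev])
  first_at <- match(ut, ts)                    # risk-set start index
  d_cnt <- as.vector(rowsum(rep(1, sum(is_ev)), ts[is_ev]))
  d0 <- as.vector(rowsum(w[is_ev], ts[is_ev]))
  d1 <- rowsum(wx[is_ev, , drop = FALSE], ts[is_ev])
  d2 <- rowsum((xx * w)[is_ev, , drop = FALSE], ts[is_ev])
  eta_sum <- as.vector(rowsum(eta[is_ev], ts[is_ev]))
  x_sum <- rowsum(xs[is_ev, , drop = FALSE], ts[is_ev])

  loglik <- sum(eta_sum)
  score <- colSums(x_sum)
  info <- matrix(0, p, p)
  for (k in seq_along(ut)) {
    i <- first_at[k]
    d <- d_cnt[k]
    s0r <- rc0[i]
    s1r <- rc1[i, ]
    s2r <- matrix(rc2[i, ], p, p)
    s2d <- matrix(d2[k, ], p, p)
    for (l in seq_len(d) - 1) {
      f <- l / d
      phi <- s0r - f * d0[k]
      mu <- (s1r - f * d1[k, ]) / phi
      loglik <- loglik - log(phi)
      score <- score - mu
      info <- info + (s2r - f * s2d) / phi - tcrossprod(mu)
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Cox proportional-hazards fit (Efron ties, Newton-Raphson)
#'
#' Maximizes the Efron-approximation partial likelihood by Newton-Raphson
#' with step halving; convergence when the largest absolute score component
#' falls below `tol` (default 1e-9) or after `max_iter` iterations. Standard
#' errors are Wald, from the inverse observed information; 95% confidence
#' intervals use `exp(beta +/- 1.959964 * se)`.
#'
#' A monotone partial likelihood (perfect separation) is flagged by
#' `converged = FALSE` with a diagnostic message rather than an error. A
#' rank-deficient (collinear) design is an error.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored); at least one
#'   event required.
#' @param x Numeric design matrix (or vector for a single covariate);
#'   categorical covariates must already be dummy-coded.
#' @param tol Convergence tolerance on the score.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `wald_z`, `wald_p` (per covariate), `loglik` (converged log
#'   partial likelihood), `loglik_null`, `vcov`, `converged`, `diagnostic`,
#'   `iterations`, `n`, `n_events`.
#' @export
cox_fit <- function(time, event, x, tol = 1e-9, max_iter = 50) {
  s <- .check_surv(time, event)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != length(s$time)) stop("design matrix row count mismatch")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(s$event) < 1) stop("at least one event is required")
  if (anyNA(x) || any(!is.finite(x))) stop("design matrix must be finite")
  if (qr(x)$rank < ncol(x)) stop("collinear design matrix")

  # center columns for numerical stability; beta is unchanged
  centers <- colMeans(x)
  xc <- sweep(x, 2, centers)

  p <- ncol(x)
  beta <- numeric(p)
  q0 <- .efron_quants(beta, s$time, s$event, xc)
  loglik_null <- q0$loglik
  cur <- q0
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0
  while (iter < max_iter) {
    if (max(abs(cur$score)) < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1
    delta <- tryCatch(solve(cur$info, cur$score), error = function(e) NULL)
    if (is.null(delta)) {
      diagnostic <- "singular information matrix"
      break
    }
    step <- 1
    repeat {
      cand <- beta + step * delta
      qc <- .efron_quants(cand, s$time, s$event, xc)
      if (is.finite(qc$loglik) && qc$loglik >= cur$loglik - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- cand
    cur <- qc
    if (max(abs(beta)) > 20) {
      diagnostic <- paste0(
        "coefficient diverging (|beta| > 20): possible monotone partial ",
        "likelihood / perfect separation")
      break
    }
  }
  if (!converged && is.null(diagnostic)) {
    if (max(abs(cur$score)) < tol) {
      converged <- TRUE
    } else {
      diagnostic <- "maximum iterations reached without convergence"
    }
  }

  vcov <- tryCatch(solve(cur$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(vcov))
  z <- 1.959964
  wald_z <- beta / se
  fit <- list(
    coef = setNames(beta, colnames(x)),
    se = setNames(se, colnames(x)),
    hr = setNames(exp(beta), colnames(x)),
    ci_lower = setNames(exp(beta - z * se), colnames(x)),
    ci_upper = setNames(exp(beta + z * se), colnames(x)),
    wald_z = setNames(wald_z, colnames(x)),
    wald_p = setNames(2 * pnorm(abs(wald_z), lower.tail = FALSE),
                      colnames(x)),
    loglik = cur$loglik, loglik_null = loglik_null,
    vcov = vcov, converged = converged, diagnostic = diagnostic,
    iterations = iter, n = length(s$time), n_events = sum(s$event)
  )
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  tab <- data.frame(coef = x$coef, HR = x$hr, `lower .95` = x$ci_lower,
                    `upper .95` = x$ci_upper, se = x$se, p = x$wald_p,
                    check.names = FALSE)
  print(tab, digits = 4)
  if (!x$converged) {
    cat("NOT converged:", x$diagnostic %||% "", "\n")
  }
  invisible(x)
}

# Joint Wald chi-square test on a block of coefficients.
.wald_block_test <- function(fit, idx) {
  b <- fit$coef[idx]
  vb <- fit$vcov[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(vb, b)), error = function(e) NA_real_)
  list(statistic = stat, df = length(idx),
       p = pchisq(stat, df = length(idx), lower.tail = FALSE))
}

#' Subtype-adjusted prognostic analysis of a marker
#'
#' Fits a multivariate Cox model of survival on the marker (continuous, or
#' dichotomized at the cohort median) plus molecular-subtype indicators
#' dummy-coded against a reference level, and reports the marker hazard
#' ratio, every subtype contrast versus the reference, and an overall test
#' of the joint subtype block (Wald chi-square by default, likelihood ratio
#' optionally).
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param marker Numeric marker expression per sample.
#' @param subtype Subtype label per sample (no missing values).
#' @param mode `"dichotomized"` (High-vs-Low at the median; default) or
#'   `"continuous"` (per expression unit).
#' @param reference Reference subtype for the contrasts (default
#'   `"Mesenchymal"`).
#' @param overall_test `"wald"` (default) or `"lrt"` for the joint subtype
#'   block test.
#' @return A list of class `subtype_adjusted_fit`:
#'   * `table`: data frame with one marker row, one subtype-overall row, and
#'     one contrast row per non-reference subtype (`term`, `hr`, `ci_lower`,
#'     `ci_upper`, `p`, `unstable` — flagged for subtypes with zero events);
#'   * `fit`: the underlying [cox_fit()];
#'   * `overall_p`, `mode`, `reference`.
#' @export
subtype_adjusted_analysis <- function(time, event, marker, subtype,
                                      mode = c("dichotomized", "continuous"),
                                      reference = "Mesenchymal",
                                      overall_test = c("wald", "lrt")) {
  mode <- match.arg(mode)
  overall_test <- match.arg(overall_test)
  s <- .check_surv(time, event)
  subtype <- as.character(subtype)
  if (anyNA(subtype)) stop("every sample needs a subtype assignment")
  if (length(subtype) != length(s$time) ||
      length(marker) != length(s$time)) {
    stop("marker/subtype length mismatch")
  }
  levs <- sort(unique(subtype))
  if (!reference %in% levs) {
    stop("reference subtype '", reference, "' not present; found: ",
         paste(levs, collapse = ", "))
  }
  others <- setdiff(levs, reference)

  if (mode == "dichotomized") {
    grp <- median_dichotomize(marker)
    marker_cov <- as.numeric(grp == "High")
    marker_term <- "marker High vs. Low"
  } else {
    marker_cov <- as.numeric(marker)
    marker_term <- "marker (continuous)"
  }
  x <- cbind(marker = marker_cov,
             vapply(others, function(l) as.numeric(subtype == l),
                    numeric(length(subtype))))
  colnames(x) <- c("marker", others)
  fit <- cox_fit(s$time, s$event, x)

  sub_idx <- which(colnames(x) %in% others)
  if (length(sub_idx)) {
    if (overall_test == "wald") {
      ov <- .wald_block_test(fit, sub_idx)
    } else {
      fit0 <- cox_fit(s$time, s$event, x[, "marker", drop = FALSE])
      stat <- 2 * (fit$loglik - fit0$loglik)
      ov <- list(statistic = stat, df = length(sub_idx),
                 p = pchisq(stat, df = length(sub_idx), lower.tail = FALSE))
    }
  } else {
    ov <- list(statistic = NA_real_, df = 0L, p = NA_real_)
  }

  events_by <- tapply(s$event, subtype, sum)
  unstable_levels <- names(events_by)[events_by == 0]

  rows <- list(
    data.frame(term = marker_term, hr = fit$hr[["marker"]],
               ci_lower = fit$ci_lower[["marker"]],
               ci_upper = fit$ci_upper[["marker"]],
               p = fit$wald_p[["marker"]], unstable = FALSE,
               stringsAsFactors = FALSE),
    data.frame(term = "Subtype (overall)", hr = NA_real_,
               ci_lower = NA_real_, ci_upper = NA_real_, p = ov$p,
               unstable = FALSE, stringsAsFactors = FALSE)
  )
  for (l in others) {
    rows[[length(rows) + 1]] <- data.frame(
      term = paste0(l, " vs. ", reference),
      hr = fit$hr[[l]], ci_lower = fit$ci_lower[[l]],
      ci_upper = fit$ci_upper[[l]], p = fit$wald_p[[l]],
      unstable = l %in% unstable_levels || reference %in% unstable_levels,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, overall_p = ov$p,
                 overall_statistic = ov$statistic, overall_df = ov$df,
                 mode = mode, reference = reference),
            class = "subtype_adjusted_fit")
}

#' @export
print.subtype_adjusted_fit <- function(x, ...) {
  cat("Subtype-adjusted Cox analysis (", x$mode, " marker, reference ",
      x$reference, ")\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Univariate prognostic summary of a marker
#'
#' The marker's unadjusted prognostic read-out: median dichotomization,
#' Kaplan-Meier curves, log-rank test, and univariate Cox fits with the
#' marker both dichotomized and continuous.
#'
#' @inheritParams subtype_adjusted_analysis
#' @return List with `km` (per-group curves), `logrank`, `cox_dichotomized`,
#'   `cox_continuous`, and `marker_group` (the High/Low factor).
#' @export
univariate_marker_analysis <- function(time, event, marker) {
  s <- .check_surv(time, event)
  grp <- median_dichotomize(marker)
  km <- km_curve(s$time, s$event, grp)
  lr <- logrank_test(s$time, s$event, grp)
  fit_d <- cox_fit(s$time, s$event,
                   cbind(marker_high = as.numeric(grp == "High")))
  fit_c <- cox_fit(s$time, s$event, cbind(marker = as.numeric(marker)))
  list(km = km, logrank = lr, cox_dichotomized = fit_d,
       cox_continuous = fit_c, marker_group = grp)
}
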