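#' Kaplan-Meier product-limit estimate
#'
#' Censored observations leave the risk set without contributing an event.
#' The returned table has one row per distinct event time; the survival
#' function is 1 before the first event and steps down at each event time.
#' Greenwood's formula supplies the variance.
#'
#' @param times positive observation times.
#' @param events 0/1 event indicators.
#' @return A data.frame of class `pv_km` with columns `time`, `n_risk`,
#'   `n_event`, `surv`, `var` (Greenwood), `se`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("no observations")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1),
                    numeric(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  var <- surv^2 * gw
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    surv = surv, var = var, se = sqrt(var))
  class(out) <- c("pv_km", "data.frame")
  attr(out, "n") <- length(times)
  out
}

#' Survival probability from a Kaplan-Meier curve at given times
#' @param curve a `pv_km` table.
#' @param t times at which to evaluate the step function.
#' @return Numeric survival probabilities.
#' @export
km_survprob <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square statistic on one degree of
#' freedom, tabulated over the distinct event times.  With no events
#' anywhere the statistic is 0 and p = 1 (with a warning).
#'
#' @param times positive observation times.
#' @param events 0/1 event indicators.
#' @param groups two-level grouping (anything coercible to factor).
#' @return A list with `statistic`, `p`, `observed` and `expected` event
#'   counts per group.
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly 2 groups required")
  if (any(table(g) == 0L)) stop("both groups must be non-empty")
  stopifnot(length(times) == length(events),
            length(times) == length(g))
  if (sum(events) == 0) {
    warning("no events; log-rank statistic undefined, returning p = 1")
    return(list(statistic = 0, p = 1,
                observed = c(0, 0), expected = c(0, 0)))
  }
  in1 <- g == levels(g)[2L]
  ev_times <- sort(unique(times[events == 1]))
  U <- 0
  V <- 0
  O1 <- 0
  E1 <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in1)
    e1 <- d * n1 / n
    U <- U + (d1 - e1)
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    O1 <- O1 + d1
    E1 <- E1 + e1
  }
  stat <- if (V > 0) U^2 / V else 0
  total_events <- sum(events)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(total_events - O1, O1),
       expected = c(total_events - E1, E1))
}

# --- internal single-binary-covariate Cox machinery -----------------------
# Precomputes the risk-set layout once so thousands of genes can be scanned
# against the same survival data cheaply.
cox_risk_structure <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  ord <- order(times)
  t_s <- times[ord]
  e_s <- as.integer(events[ord])
  ev_times <- unique(t_s[e_s == 1L])
  first_idx <- match(ev_times, t_s)  # risk set = suffix of the sort order
  n <- length(t_s)
  grp <- match(t_s, ev_times)        # NA for times that are no event time
  ev_mask <- e_s == 1L
  d <- as.vector(rowsum(rep(1L, sum(ev_mask)),
                        grp[ev_mask]))  # deaths per distinct event time
  list(ord = ord, t_s = t_s, e_s = e_s, ev_times = ev_times,
       first_idx = first_idx, n_at = n - first_idx + 1,
       grp_event = grp[ev_mask], ev_mask = ev_mask, d = d, n = n)
}

# Newton-Raphson maximizer of the Breslow partial likelihood for one
# binary covariate.  Returns beta, se, iterations; flags separation.
cox_fit_binary <- function(x, struct) {
  x_s <- as.numeric(x[struct$ord])
  sx <- rev(cumsum(rev(x_s)))
  n1 <- sx[struct$first_idx]
  n0 <- struct$n_at - n1
  d1 <- as.vector(rowsum(x_s[struct$ev_mask], struct$grp_event))
  d <- struct$d
  sum_d1 <- sum(d1)
  beta <- 0
  for (iter in seq_len(30L)) {
    eb <- exp(beta)
    denom <- n0 + n1 * eb
    mu <- n1 * eb / denom
    U <- sum_d1 - sum(d * mu)
    I <- sum(d * mu * (1 - mu))
    if (I <= 0) return(list(beta = NA_real_, se = NA_real_,
                            converged = FALSE))
    step <- U / I
    if (!is.finite(step)) return(list(beta = NA_real_, se = NA_real_,
                                      converged = FALSE))
    step <- max(min(step, 5), -5)  # damp huge first steps
    beta <- beta + step
    if (abs(beta) > 15) {
      return(list(beta = beta, se = NA_real_, converged = FALSE))
    }
    if (abs(step) < 1e-10) break
  }
  eb <- exp(beta)
  denom <- n0 + n1 * eb
  mu <- n1 * eb / denom
  I <- sum(d * mu * (1 - mu))
  list(beta = beta, se = 1 / sqrt(I), converged = TRUE)
}

#' Unadjusted Cox proportional-hazards model for a binary group
#'
#' Maximizes the Breslow-ties partial likelihood for a single binary
#' covariate by Newton-Raphson and reports the hazard ratio with a Wald
#' 95% confidence interval on the log scale and the Wald p-value.
#' Complete separation (all events in one group while the other remains
#' at risk) makes the partial likelihood monotone; this is flagged as
#' non-convergence and raised as an error.
#'
#' @param times positive observation times.
#' @param events 0/1 event indicators (at least one event).
#' @param group_indicator binary group membership (0/1, logical, or a
#'   2-level factor; the second level / value 1 is the numerator group).
#' @return A list of class `pv_hr`: `hr`, `ci_low`, `ci_high`, `p`,
#'   `beta`, `se`, `n`, `events`.
#' @export
cox_binary_hr <- function(times, events, group_indicator) {
  x <- group_indicator
  if (is.factor(x)) x <- as.integer(x) - 1L
  x <- as.numeric(x)
  if (!all(x %in% c(0, 1))) stop("group_indicator must be binary")
  if (length(unique(x)) < 2L) stop("both groups must be present")
  if (sum(events) == 0) stop("no events; hazard ratio undefined")
  struct <- cox_risk_structure(times, events)
  fit <- cox_fit_binary(x, struct)
  if (!isTRUE(fit$converged)) {
    stop("Cox model did not converge (complete separation?)")
  }
  z <- qnorm(0.975)
  structure(list(hr = exp(fit$beta),
                 ci_low = exp(fit$beta - z * fit$se),
                 ci_high = exp(fit$beta + z * fit$se),
                 p = 2 * pnorm(-abs(fit$beta / fit$se)),
                 beta = fit$beta, se = fit$se,
                 n = length(times), events = sum(events)),
            class = "pv_hr")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i`, cumulative-minimized from
#' the largest rank down and capped at 1.  Never decreases a p-value and
#' preserves the step-up significance set.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.002))  # 0.02 0.04 0.04 0.008
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  ord <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(pvalues[ord] * m / seq(m, 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' ROC curve and AUC
#'
#' AUC is the probability that a randomly chosen positive (death / poor
#' prognosis) receives a higher score than a randomly chosen negative,
#' with ties counted one half — the rank-statistic form, identical to
#' trapezoidal integration of the ROC curve.
#'
#' @param probabilities numeric scores (higher = more likely positive).
#' @param labels 0/1 with 1 the positive class; both classes required.
#' @return A list with `auc` and `points` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(probabilities)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) {
      sum(probabilities >= t & labels == 0) / n0
    }, numeric(1))),
    tpr = c(0, vapply(thr, function(t) {
      sum(probabilities >= t & labels == 1) / n1
    }, numeric(1)))
  )
  list(auc = auc, points = pts)
}

#' Confusion-matrix metrics for prognosis classification
#'
#' Positive class is death within the horizon: a patient who died is a
#' true positive when assigned to the poor-prognosis group, a false
#' negative otherwise; a patient alive at the horizon is a true negative
#' when assigned to the good-prognosis group, a false positive otherwise.
#'
#' @param predicted predicted poor-prognosis calls: 0/1, logical, or a
#'   factor with levels including `"poor"`.
#' @param truth 0/1 death indicators.
#' @return A list of class `pv_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (is.factor(predicted) || is.character(predicted)) {
    predicted <- as.integer(as.character(predicted) == "poor")
  }
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  stopifnot(all(predicted %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  tn <- sum(predicted == 0L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 accuracy = (tp + tn) / length(truth)),
            class = "pv_confusion")
}

#' Paired t-test on log2 hazard ratios
#'
#' Compares two matched sets of hazard ratios on the log2 scale.  When the
#' paired differences have zero variance the t statistic is degenerate
#' (infinite for a constant non-zero shift, undefined for identical
#' lists); this is flagged rather than reported as a p-value.
#'
#' @param hr_list_a,hr_list_b equal-length vectors of positive hazard
#'   ratios (n >= 2).
#' @return A list with `t`, `df`, `p`, `mean_diff` (mean log2 difference
#'   a - b) and `degenerate`.
#' @export
compare_log2_hr_paired <- function(hr_list_a, hr_list_b) {
  stopifnot(length(hr_list_a) == length(hr_list_b),
            length(hr_list_a) >= 2L,
            all(hr_list_a > 0), all(hr_list_b > 0))
  d <- log2(hr_list_a) - log2(hr_list_b)
  n <- length(d)
  s <- sd(d)
  # a spread at rounding-error scale relative to the differences is a
  # constant shift, not evidence
  if (s <= 1e-10 * max(abs(d), 1)) {
    t_stat <- if (mean(d) == 0) NA_real_ else sign(mean(d)) * Inf
    return(list(t = t_stat, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * pt(-abs(t_stat), df = n - 1L),
       mean_diff = mean(d), degenerate = FALSE)
}
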