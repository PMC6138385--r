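#' Evaluate a prognosis classifier against survival data
#'
#' Builds the full evaluation report for any set of per-patient
#' poor-prognosis calls: unadjusted Cox hazard ratio (poor vs good) with
#' 95% CI and Wald p, the log-rank test, Kaplan-Meier curves per risk
#' group, confusion metrics against death-by-horizon status, and — when
#' classification probabilities are supplied — the ROC AUC.  Patients not
#' present in `predicted` (for example those the unanimous classifier
#' leaves unclassified) are simply excluded from the evaluation.
#'
#' @param predicted named vector of poor-prognosis calls (names = patient
#'   ids): 0/1, logical, or factor with level `"poor"`.
#' @param survival_table a `pv_survival` table.
#' @param probability optional named vector of poor-prognosis
#'   probabilities for the same patients (enables AUC).
#' @param horizon_years horizon for the binary death status; default 5.
#' @return A list of class `pv_report`: `n`, `n_poor`, `n_good`, `hr`,
#'   `logrank`, `confusion`, `auc` (or `NULL`), and `km` (list of
#'   Kaplan-Meier tables named `poor` and `good`).
#' @export
evaluate_classifier <- function(predicted, survival_table,
                                probability = NULL, horizon_years = 5) {
  if (is.null(names(predicted))) {
    stop("predicted must be named by patient id")
  }
  if (is.factor(predicted) || is.character(predicted)) {
    keep <- as.character(predicted) %in% c("poor", "good")
    predicted <- predicted[keep]
    poor <- as.integer(as.character(predicted) == "poor")
  } else {
    poor <- as.integer(predicted)
  }
  names(poor) <- names(predicted)
  idx <- match(names(poor), survival_table$patient_id)
  if (anyNA(idx)) stop("predicted patients missing from survival table")
  st <- survival_table[idx, , drop = FALSE]
  outcome <- make_binary_outcome(st, horizon_years)
  hr <- cox_binary_hr(st$time_years, st$event, poor)
  lr <- logrank_test(st$time_years, st$event, poor)
  km <- list(
    good = km_estimate(st$time_years[poor == 0L], st$event[poor == 0L]),
    poor = km_estimate(st$time_years[poor == 1L], st$event[poor == 1L])
  )
  conf <- confusion_metrics(poor, outcome$death)
  auc <- NULL
  if (!is.null(probability)) {
    prob <- probability[names(poor)]
    auc <- roc_auc(prob, outcome$death)$auc
  }
  structure(list(n = length(poor), n_poor = sum(poor == 1L),
                 n_good = sum(poor == 0L),
                 hr = unclass(hr), logrank = lr,
                 confusion = unclass(conf), auc = auc, km = km),
            class = c("pv_report", "list"))
}

#' @export
print.pv_report <- function(x, ...) {
  cat(sprintf("prepvote evaluation (n = %d; poor %d / good %d)\n",
              x$n, x$n_poor, x$n_good))
  cat(sprintf("  HR %.2f (95%% CI %.2f-%.2f), Wald p = %.3g\n",
              x$hr$hr, x$hr$ci_low, x$hr$ci_high, x$hr$p))
  cat(sprintf("  log-rank chi2 = %.2f, p = %.3g\n",
              x$logrank$statistic, x$logrank$p))
  cat(sprintf("  accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$confusion$accuracy, x$confusion$sensitivity,
              x$confusion$specificity))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}
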