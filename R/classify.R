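#' Binarize survival outcome at a horizon
#'
#' Label 0 means the patient died (event) at or before the horizon; label 1
#' means alive at the horizon.  Events occurring after the horizon are
#' treated as censored at the horizon (hence alive).  Patients censored
#' before the horizon are, by default, also labeled alive — the overridable
#' convention implied by cohort-level event accounting — or can be
#' excluded.
#'
#' @param survival_table a `pv_survival` table.
#' @param horizon_years horizon (> 0); default 5.
#' @param censored_before_horizon `"alive"` (default) or `"exclude"`.
#' @return A data.frame with `patient_id`, `label` (1 = alive, 0 = dead)
#'   and `death` (`1 - label`, the positive class for classification).
#' @export
make_binary_outcome <- function(survival_table, horizon_years = 5,
                                censored_before_horizon = c("alive",
                                                            "exclude")) {
  censored_before_horizon <- match.arg(censored_before_horizon)
  stopifnot(horizon_years > 0)
  died <- survival_table$event == 1L &
    survival_table$time_years <= horizon_years
  out <- data.frame(patient_id = survival_table$patient_id,
                    label = as.integer(!died),
                    death = as.integer(died),
                    stringsAsFactors = FALSE)
  if (censored_before_horizon == "exclude") {
    drop <- survival_table$event == 0L &
      survival_table$time_years < horizon_years
    if (any(drop)) {
      pv_log("info", sprintf("excluding %d patients censored before horizon",
                             sum(drop)))
    }
    out <- out[!drop, , drop = FALSE]
  }
  out
}

#' Stratified train/test split
#'
#' Randomly splits patients into training and testing halves while keeping
#' the death/survival class balance: within each class the training set
#' receives `floor(ratio * n_class)` patients, so per-class counts in the
#' two halves differ by at most one, with the seeded permutation deciding
#' which patients (and which half the odd patient of an odd class joins).
#'
#' @param outcome data.frame from [make_binary_outcome()].
#' @param ratio training fraction in (0, 1); default 0.5 (a 1:1 split).
#' @param seed integer seed.
#' @return A list with character vectors `train` and `test` of patient
#'   ids.
#' @export
split_train_test <- function(outcome, ratio = 0.5, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  classes <- split(outcome$patient_id, outcome$label)
  if (length(classes) < 2L) stop("both outcome classes must be present")
  if (any(lengths(classes) < 2L)) {
    stop("each outcome class needs at least 2 patients to split")
  }
  set.seed(seed)
  train <- unlist(lapply(classes, function(ids) {
    ids[sample.int(length(ids))[seq_len(floor(ratio * length(ids)))]]
  }), use.names = FALSE)
  list(train = sort(train),
       test = sort(setdiff(outcome$patient_id, train)))
}

#' Assemble a classifier feature matrix
#'
#' Builds the feature combinations used for ensemble classification:
#' pipeline votes only, votes plus the 12 engineered counts, engineered
#' counts only, or the Boruta-confirmed subset of votes + engineered.
#'
#' @param vote_matrix patients x pipelines 0/1 matrix.
#' @param engineered data.frame from [engineer_vote_features()].
#' @param set one of `"votes"`, `"votes+eng"`, `"eng"`, `"boruta"`.
#' @param boruta_features for `set = "boruta"`, the confirmed feature
#'   names (from [boruta_select()] run on the votes+engineered matrix).
#' @return Numeric matrix, patients in rows.
#' @export
assemble_features <- function(vote_matrix, engineered = NULL,
                              set = c("votes", "votes+eng", "eng",
                                      "boruta"),
                              boruta_features = NULL) {
  set <- match.arg(set)
  if (set != "votes" && is.null(engineered)) {
    stop("engineered features required for set '", set, "'")
  }
  eng <- NULL
  if (!is.null(engineered)) {
    eng <- as.matrix(engineered[, setdiff(names(engineered),
                                          "patient_id"), drop = FALSE])
    rownames(eng) <- engineered$patient_id
    eng <- eng[rownames(vote_matrix), , drop = FALSE]
  }
  out <- switch(set,
                "votes" = vote_matrix,
                "votes+eng" = cbind(vote_matrix, eng),
                "eng" = eng,
                "boruta" = {
                  if (is.null(boruta_features)) {
                    stop("boruta_features must be supplied for set 'boruta'")
                  }
                  cbind(vote_matrix, eng)[, boruta_features, drop = FALSE]
                })
  storage.mode(out) <- "double"
  out
}

#' Tune a tree ensemble over an (mtry, ntree) grid
#'
#' Trains one forest per grid combination on the training half and scores
#' accuracy on the evaluation half (the held-out test set by default, the
#' faithful — if leaky — protocol; `eval_on = "oob"` uses out-of-bag
#' accuracy on the training half instead).  The combination with the
#' highest accuracy wins; ties go to the smaller `mtry`, then the smaller
#' `ntree`, so the result is invariant to grid ordering.  Grid `mtry`
#' values exceeding the feature count are dropped with a warning.
#'
#' @param features numeric matrix, patients in rows (named).
#' @param labels named 0/1 vector (1 = death / positive class) covering
#'   all patients in `partition`.
#' @param partition list with `train` / `test` patient ids, from
#'   [split_train_test()].
#' @param mtry_grid,ntree_grid candidate values (non-empty).
#' @param seed integer seed; each combination trains from its own derived
#'   sub-seed, so results do not depend on grid order.
#' @param eval_on `"test"` or `"oob"`.
#' @param ... passed to [train_tree_ensemble()].
#' @return A list of class `pv_classifier_result`: chosen `mtry`, `ntree`,
#'   tuning `accuracy`, the refit `model`, per-test-patient `probability`
#'   (of death) and `predicted` (1 = predicted death at the 0.5 cut),
#'   `grid` (all combinations with accuracies), and the seed.
#' @export
tune_grid <- function(features, labels, partition, mtry_grid, ntree_grid,
                      seed = 1L, eval_on = c("test", "oob"), ...) {
  eval_on <- match.arg(eval_on)
  if (length(mtry_grid) == 0L || length(ntree_grid) == 0L) {
    stop("tuning grids must be non-empty")
  }
  mtry_grid <- sort(unique(as.integer(mtry_grid)))
  ntree_grid <- sort(unique(as.integer(ntree_grid)))
  keep <- mtry_grid <= ncol(features)
  if (!all(keep)) {
    warning(sprintf("dropping mtry > %d features: %s", ncol(features),
                    paste(mtry_grid[!keep], collapse = ", ")))
    mtry_grid <- mtry_grid[keep]
  }
  if (length(mtry_grid) == 0L) stop("no valid mtry values remain")
  x_train <- features[partition$train, , drop = FALSE]
  y_train <- labels[partition$train]
  x_test <- features[partition$test, , drop = FALSE]
  y_test <- labels[partition$test]

  grid <- expand.grid(mtry = mtry_grid, ntree = ntree_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- NA_real_
  models <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    combo_seed <- derive_seed(seed,
                              sprintf("tune_%d_%d", grid$mtry[k],
                                      grid$ntree[k]))
    fit <- train_tree_ensemble(x_train, y_train, mtry = grid$mtry[k],
                               ntree = grid$ntree[k], seed = combo_seed,
                               ...)
    if (eval_on == "test") {
      pred <- predict(fit, x_test, type = "class")
      grid$accuracy[k] <- mean(pred == y_test)
    } else {
      oob <- fit$oob_prob
      ok <- !is.na(oob)
      grid$accuracy[k] <- mean(as.integer(oob[ok] > 0.5) == y_train[ok])
    }
    models[[k]] <- fit
  }
  # highest accuracy; ties -> smaller mtry, then smaller ntree
  ord <- order(-grid$accuracy, grid$mtry, grid$ntree)
  best <- ord[1L]
  model <- models[[best]]
  prob <- predict(model, x_test, type = "prob")
  structure(list(mtry = grid$mtry[best], ntree = grid$ntree[best],
                 accuracy = grid$accuracy[best], model = model,
                 probability = prob,
                 predicted = as.integer(prob > 0.5),
                 test_ids = partition$test, grid = grid,
                 eval_on = eval_on, seed = as.integer(seed)),
            class = "pv_classifier_result")
}

#' Boruta all-relevant feature selection
#'
#' Iteratively appends shuffled "shadow" copies of the not-yet-rejected
#' features (padded to a minimum of five so the shadow benchmark stays
#' meaningful late in the run),
#' trains the tree ensemble with out-of-bag permutation importance, and
#' counts a "hit" for each undecided feature whose importance Z-score
#' exceeds the best shadow's.  Accumulated hits are tested against a
#' Binomial(iterations, 1/2) null with a two-sided test at level `alpha`,
#' Bonferroni-adjusted for the number of features (the reference
#' implementation's default; without the adjustment pure-noise features
#' are regularly confirmed by chance): significantly many hits confirms a
#' feature, significantly few rejects it.  Features still undecided after
#' `max_iter` iterations are resolved by comparing their median importance
#' across iterations to the median of the per-iteration best-shadow
#' importance.
#'
#' Note the exact binomial test cannot confirm anything before iteration
#' `ceiling(log2(2 * p / alpha))` with `p` features, however strong the
#' feature (13 iterations at the defaults with 25 features).
#'
#' @param features numeric matrix or data.frame, samples in rows, named
#'   columns.
#' @param labels 0/1 vector (1 = positive class).
#' @param max_iter maximum iterations; default 100.
#' @param alpha two-sided binomial test level; default 0.01.
#' @param seed integer seed.
#' @param ntree trees per internal forest; default 300.
#' @return Character vector of confirmed feature names, with attributes
#'   `decision` (named factor `confirmed`/`rejected`) and `n_iter`.
#' @export
boruta_select <- function(features, labels, max_iter = 100L, alpha = 0.01,
                          seed = 1L, ntree = 300L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) stop("need at least 2 features")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- ncol(x)
  if (all(apply(x, 2L, function(v) length(unique(v)) == 1L))) {
    warning("all features constant; nothing to select")
    dec <- factor(rep("rejected", p),
                  levels = c("confirmed", "rejected"))
    names(dec) <- colnames(x)
    return(structure(character(0), decision = dec, n_iter = 0L))
  }
  status <- rep("tentative", p)
  names(status) <- colnames(x)
  hits <- integer(p)
  trials <- integer(p)
  names(hits) <- names(trials) <- colnames(x)
  z_hist <- matrix(NA_real_, nrow = max_iter, ncol = p,
                   dimnames = list(NULL, colnames(x)))
  shadow_max_hist <- rep(NA_real_, max_iter)
  iter <- 0L
  for (i in seq_len(max_iter)) {
    und <- names(status)[status == "tentative"]
    if (length(und) == 0L) break
    iter <- i
    set.seed(derive_seed(seed, paste0("boruta_", i)))
    keep <- names(status)[status != "rejected"]
    # shadows of every non-rejected feature (padded to at least 5) keep
    # the max-shadow benchmark strong even when few remain undecided
    shadow_src <- keep
    while (length(shadow_src) < 5L) {
      shadow_src <- c(shadow_src,
                      keep[sample.int(length(keep), 1L)])
    }
    shadows <- apply(x[, shadow_src, drop = FALSE], 2L, sample)
    colnames(shadows) <- paste0("shadow_", seq_along(shadow_src))
    xm <- cbind(x[, keep, drop = FALSE], shadows)
    fit <- train_tree_ensemble(
      xm, labels, mtry = max(1L, floor(sqrt(ncol(xm)))), ntree = ntree,
      seed = derive_seed(seed, paste0("boruta_forest_", i)),
      importance = TRUE)
    z <- fit$importance$z
    names(z) <- fit$importance$feature
    shadow_max <- max(z[startsWith(names(z), "shadow_")])
    shadow_max_hist[i] <- shadow_max
    z_hist[i, keep] <- z[keep]
    hit <- z[und] > shadow_max
    hits[und] <- hits[und] + as.integer(hit)
    trials[und] <- trials[und] + 1L
    p_hi <- pbinom(hits[und] - 1L, trials[und], 0.5, lower.tail = FALSE)
    p_lo <- pbinom(hits[und], trials[und], 0.5)
    alpha_adj <- alpha / p  # Bonferroni over the tested features
    status[und[2 * p_hi < alpha_adj]] <- "confirmed"
    status[und[2 * p_lo < alpha_adj]] <- "rejected"
  }
  # resolve remaining tentative features against the shadow record
  und <- names(status)[status == "tentative"]
  if (length(und) > 0L) {
    med_shadow <- median(shadow_max_hist, na.rm = TRUE)
    for (f in und) {
      status[f] <- if (median(z_hist[, f], na.rm = TRUE) > med_shadow) {
        "confirmed"
      } else "rejected"
    }
  }
  dec <- factor(status, levels = c("confirmed", "rejected"))
  names(dec) <- names(status)
  confirmed <- names(status)[status == "confirmed"]
  pv_log("info", sprintf("Boruta: %d/%d features confirmed in %d iterations",
                         length(confirmed), p, iter))
  structure(confirmed, decision = dec, n_iter = iter)
}
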