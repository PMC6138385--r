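#' Train a bootstrap-aggregated decision-tree ensemble
#'
#' A compact random-forest classifier for binary labels: `ntree` CART
#' trees grown on class-balanced bootstrap samples (an equal number drawn
#' with replacement from each class, equal to the minority-class count, so
#' rare events are not swamped), with `mtry` features sampled at random at
#' every node and Gini splits.  The ensemble probability for a sample is
#' the fraction of trees voting class 1.  Out-of-bag votes are tracked at
#' training time, and optional out-of-bag permutation importance supplies
#' the Z-scores the Boruta procedure needs.
#'
#' @param features numeric matrix or data.frame, samples in rows.
#' @param labels 0/1 vector, 1 being the positive (event / poor
#'   prognosis) class; both classes must be present.
#' @param mtry features tried per split (`<= ncol(features)`).
#' @param ntree number of trees (>= 1).
#' @param seed integer seed; the forest is deterministic given it.
#' @param min_node minimum samples per terminal node.
#' @param max_depth maximum tree depth.
#' @param importance compute out-of-bag permutation importance?
#' @return An object of class `pv_forest` with elements `trees`,
#'   `oob_prob` (out-of-bag class-1 vote fraction per training sample),
#'   `inbag_count` (number of times each sample was drawn across all
#'   bags),
#'   `importance` (data.frame with `mean`, `sd`, `z` per feature when
#'   requested) and the training metadata.
#' @export
train_tree_ensemble <- function(features, labels, mtry, ntree, seed = 1L,
                                min_node = 1L, max_depth = 25L,
                                importance = FALSE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; cannot train")
  }
  if (mtry < 1L || mtry > ncol(x)) {
    stop(sprintf("mtry (%d) must be in [1, %d]", mtry, ncol(x)))
  }
  if (ntree < 1L) stop("ntree must be >= 1")
  sampsize <- min(sum(y == 0L), sum(y == 1L))
  fit <- .rf_build(x, y, as.integer(ntree), as.integer(mtry),
                   as.integer(sampsize), as.integer(min_node),
                   as.integer(max_depth), as.integer(seed),
                   isTRUE(importance))
  oob_prob <- ifelse(fit$oob_count > 0,
                     fit$oob_votes1 / fit$oob_count, NA_real_)
  imp <- NULL
  if (importance) {
    z <- ifelse(fit$imp_sd > 0,
                fit$imp_mean / (fit$imp_sd / sqrt(ntree)), 0)
    imp <- data.frame(feature = colnames(x), mean = fit$imp_mean,
                      sd = fit$imp_sd, z = z, stringsAsFactors = FALSE)
  }
  structure(list(trees = fit$trees, mtry = as.integer(mtry),
                 ntree = as.integer(ntree), seed = as.integer(seed),
                 sampsize_per_class = sampsize,
                 inbag_count = fit$inbag_count,
                 feature_names = colnames(x), oob_prob = oob_prob,
                 importance = imp),
            class = "pv_forest")
}

#' Predict from a tree ensemble
#'
#' @param object a `pv_forest`.
#' @param newdata matrix or data.frame with the training feature columns.
#' @param type `"prob"` for the class-1 vote fraction, `"class"` for the
#'   0/1 label at the 0.5 cut (probability strictly greater than 0.5 maps
#'   to 1).
#' @param ... unused.
#' @return Numeric probabilities or integer labels.
#' @export
predict.pv_forest <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    if (!all(object$feature_names %in% colnames(x))) {
      stop("newdata lacks training feature columns")
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  prob <- .rf_predict(object$trees, x)
  names(prob) <- rownames(x)
  if (type == "prob") prob else as.integer(prob > 0.5)
}
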