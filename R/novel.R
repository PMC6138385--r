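#' Univariate Cox scan over all genes of one abundance matrix
#'
#' For every gene, patients are median-dichotomized on that gene's
#' abundance and an unadjusted Breslow Cox model is fitted to the
#' dichotomy, giving a per-gene hazard ratio and Wald p-value; p-values
#' are then Benjamini-Hochberg adjusted across genes.  Genes whose
#' dichotomy is constant (more than half the cohort tied at the median)
#' and genes whose fit does not converge are skipped with one summary
#' warning.  The risk-set layout is computed once, so scanning thousands
#' of genes is cheap.
#'
#' @param matrix genes x patients abundance matrix.
#' @param survival_table a `pv_survival` table covering the matrix
#'   patients.
#' @return A data.frame with columns `gene`, `beta`, `hr`, `wald_p`,
#'   `fdr_p`, `rank`, ordered by rank (ascending adjusted then raw p).
#' @export
per_gene_cox_scan <- function(matrix, survival_table) {
  patients <- colnames(matrix)
  idx <- match(patients, survival_table$patient_id)
  if (anyNA(idx)) stop("matrix patients missing from survival table")
  st <- survival_table[idx, , drop = FALSE]
  if (sum(st$event) == 0) stop("no events; cannot scan genes")
  struct <- cox_risk_structure(st$time_years, st$event)
  n_genes <- nrow(matrix)
  beta <- se <- rep(NA_real_, n_genes)
  skipped_const <- skipped_fit <- character(0)
  for (g in seq_len(n_genes)) {
    x <- median_dichotomize(matrix[g, ])
    if (length(unique(x)) < 2L) {
      skipped_const <- c(skipped_const, rownames(matrix)[g])
      next
    }
    fit <- cox_fit_binary(x, struct)
    if (!isTRUE(fit$converged)) {
      skipped_fit <- c(skipped_fit, rownames(matrix)[g])
      next
    }
    beta[g] <- fit$beta
    se[g] <- fit$se
  }
  if (length(skipped_const)) {
    warning(sprintf("%d constant gene dichotomies skipped (e.g. %s)",
                    length(skipped_const), skipped_const[1L]))
  }
  if (length(skipped_fit)) {
    warning(sprintf("%d genes skipped for non-convergence (e.g. %s)",
                    length(skipped_fit), skipped_fit[1L]))
  }
  ok <- !is.na(beta)
  p <- 2 * pnorm(-abs(beta[ok] / se[ok]))
  out <- data.frame(gene = rownames(matrix)[ok], beta = beta[ok],
                    hr = exp(beta[ok]), wald_p = p,
                    fdr_p = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$fdr_p, out$wald_p, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked significant genes into a signature
#'
#' Keeps the genes with adjusted p below `alpha`, ordered by rank, and
#' truncates to the `top_k` best.  When fewer than `top_k` genes pass the
#' threshold, all passing genes are returned with a warning; none passing
#' is an error.
#'
#' @param scan data.frame from [per_gene_cox_scan()].
#' @param top_k signature size cap; default 100.
#' @param alpha adjusted-p threshold; default 0.05.
#' @param name signature name.
#' @return A `pv_signature`.
#' @export
select_top_genes <- function(scan, top_k = 100L, alpha = 0.05,
                             name = "novel_signature") {
  stopifnot(top_k >= 1)
  passing <- scan[scan$fdr_p < alpha, , drop = FALSE]
  if (nrow(passing) == 0L) {
    stop("no genes pass the adjusted-p threshold")
  }
  if (nrow(passing) < top_k) {
    warning(sprintf("only %d genes pass (requested %d); keeping all",
                    nrow(passing), top_k))
  }
  gene_signature(head(passing$gene[order(passing$rank)], top_k),
                 name = name)
}

#' Cross-validated random-forest classifier for one signature
#'
#' Features are the signature genes' median-dichotomized abundances.
#' Patients are split into stratified folds (class proportions preserved);
#' for each fold a forest is trained on the remaining folds and predicts
#' the held-out patients, so every patient receives exactly one
#' out-of-fold prediction.
#'
#' @param matrix genes x patients abundance matrix.
#' @param signature a `pv_signature` (genes present in the matrix are
#'   used; absent ones warned about by [score_signature()] semantics).
#' @param outcome data.frame from [make_binary_outcome()].
#' @param folds number of folds (>= 2); default 10.
#' @param seed integer seed.
#' @param ntree trees per fold's forest; default 500.
#' @param mtry features per split; default `floor(sqrt(#genes))`.
#' @return A data.frame with `patient_id`, `fold`, `probability` (of
#'   death), `predicted` (1 = predicted death / poor prognosis).
#' @export
cross_validated_signature_classifier <- function(matrix, signature,
                                                 outcome, folds = 10L,
                                                 seed = 1L, ntree = 500L,
                                                 mtry = NULL) {
  stopifnot(folds >= 2L)
  found <- intersect(signature$genes, rownames(matrix))
  if (length(found) == 0L) stop("no signature genes found in matrix")
  common <- intersect(colnames(matrix), outcome$patient_id)
  sub <- matrix[found, common, drop = FALSE]
  feats <- t(apply(sub, 1L, median_dichotomize))
  x <- t(feats)  # patients x genes
  storage.mode(x) <- "double"
  rownames(x) <- common
  y <- outcome$death[match(common, outcome$patient_id)]
  names(y) <- common

  # stratified fold assignment
  set.seed(derive_seed(seed, "cv_folds"))
  fold_of <- integer(length(y))
  names(fold_of) <- common
  for (cls in unique(y)) {
    ids <- common[y == cls]
    fold_of[ids[sample.int(length(ids))]] <-
      rep_len(seq_len(folds), length(ids))
  }
  tab <- table(fold_of, y)
  if (any(tab == 0L)) {
    stop("a class is too rare for stratified ", folds, "-fold CV")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  prob <- rep(NA_real_, length(y))
  names(prob) <- common
  for (f in seq_len(folds)) {
    train_ids <- common[fold_of != f]
    test_ids <- common[fold_of == f]
    fit <- train_tree_ensemble(x[train_ids, , drop = FALSE],
                               y[train_ids], mtry = mtry, ntree = ntree,
                               seed = derive_seed(seed,
                                                  paste0("cv_fold_", f)))
    prob[test_ids] <- predict(fit, x[test_ids, , drop = FALSE])
  }
  data.frame(patient_id = common, fold = unname(fold_of[common]),
             probability = unname(prob),
             predicted = as.integer(prob > 0.5),
             stringsAsFactors = FALSE)
}

#' Discover one novel signature per merged-handling pipeline
#'
#' Runs [per_gene_cox_scan()] and [select_top_genes()] on every
#' merged-handling pipeline variant.  Discovery can (and for honest
#' evaluation should) be restricted to training patients via
#' `patient_subset`.
#'
#' @param matrices_by_pipeline named list of abundance matrices.
#' @param survival_table a `pv_survival` table.
#' @param specs optional `pv_pipelines` to resolve handling per id.
#' @param top_k,alpha selection parameters; defaults 100 and 0.05.
#' @param patient_subset optional patient ids to restrict discovery to.
#' @return Named list of `pv_signature`, one per merged-handling pipeline.
#' @export
discover_signatures <- function(matrices_by_pipeline, survival_table,
                                specs = NULL, top_k = 100L, alpha = 0.05,
                                patient_subset = NULL) {
  ids <- names(matrices_by_pipeline)
  if (is.null(specs)) specs <- enumerate_pipelines()
  sp <- match_pipeline_specs(ids, specs)
  merged_ids <- ids[sp$handling == "merged"]
  if (length(merged_ids) == 0L) {
    stop("no merged-handling pipelines among inputs")
  }
  out <- vector("list", length(merged_ids))
  names(out) <- merged_ids
  for (id in merged_ids) {
    m <- matrices_by_pipeline[[id]]
    if (!is.null(patient_subset)) {
      m <- m[, intersect(colnames(m), patient_subset), drop = FALSE]
    }
    scan <- per_gene_cox_scan(m, survival_table)
    out[[id]] <- select_top_genes(scan, top_k = top_k, alpha = alpha,
                                  name = paste0("novel_", id))
  }
  out
}

#' Meta-ensemble over per-pipeline signature classifications
#'
#' Stacks the binary good/poor classifications produced by the individual
#' per-pipeline signature classifiers (one column per pipeline) as
#' features of a second-level tuned tree ensemble, trained and evaluated
#' on the supplied partition like any other classifier.
#'
#' @param classifications_by_pipeline patients x pipelines 0/1 matrix of
#'   per-signature predicted-death calls (>= 2 columns, named rows).
#' @param outcome data.frame from [make_binary_outcome()].
#' @param partition list with `train`/`test` ids.
#' @param mtry_grid,ntree_grid tuning grids.
#' @param seed integer seed.
#' @return A `pv_classifier_result` from [tune_grid()].
#' @export
meta_ensemble <- function(classifications_by_pipeline, outcome, partition,
                          mtry_grid = c(1L, 2L, 4L, 6L, 8L, 10L, 12L),
                          ntree_grid = c(500L, 1000L), seed = 1L) {
  x <- as.matrix(classifications_by_pipeline)
  if (ncol(x) < 2L) stop("need at least 2 pipeline classification columns")
  storage.mode(x) <- "double"
  y <- outcome$death
  names(y) <- outcome$patient_id
  tune_grid(x, y, partition, mtry_grid = mtry_grid,
            ntree_grid = ntree_grid, seed = seed)
}

#' Per-subtype classification accuracy
#'
#' Accuracy within each intrinsic-subtype label, computed over patients
#' carrying that label; patients without subtype information are excluded
#' from every subtype row.  The `overall` row uses all labeled patients.
#' A subtype with no labeled patients is reported as `NA`, not zero.
#'
#' @param predictions named 0/1 vector of predicted death calls.
#' @param outcome data.frame from [make_binary_outcome()].
#' @param subtypes named per-patient subtype labels (NA = unknown).
#' @return A data.frame with `subtype`, `n`, `accuracy` (the last row is
#'   `overall`).
#' @export
subtype_accuracy <- function(predictions, outcome, subtypes) {
  ids <- names(predictions)
  if (is.null(ids)) stop("predictions must be named by patient id")
  truth <- outcome$death[match(ids, outcome$patient_id)]
  sub <- subtypes[ids]
  labeled <- !is.na(sub)
  correct <- as.integer(predictions) == truth
  levels <- sort(unique(sub[labeled]))
  rows <- lapply(levels, function(s) {
    sel <- labeled & sub == s
    data.frame(subtype = s, n = sum(sel),
               accuracy = if (sum(sel) > 0) mean(correct[sel]) else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  rbind(do.call(rbind, rows),
        data.frame(subtype = "overall", n = sum(labeled),
                   accuracy = if (any(labeled)) mean(correct[labeled]) else
                     NA_real_,
                   stringsAsFactors = FALSE))
}
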