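#' Default preprocessing pipeline factor levels
#'
#' The pipeline configuration space is the cross-product of three factors:
#' six normalization algorithms (four native-scale plus log2-transformed
#' variants of MAS5 and MBEI), two probe annotations (the manufacturer
#' default and an updated gene-centric alternative), and two dataset
#' handling modes (each dataset preprocessed separately, or all pooled and
#' preprocessed merged).  Crossing the defaults yields 24 pipelines.
#'
#' @name pipeline_factors
#' @keywords internal
NULL

pv_algorithms <- c("RMA", "MAS5", "MBEI", "GCRMA", "MAS5_log2", "MBEI_log2")
pv_annotations <- c("default", "alternative")
pv_handlings <- c("separate", "merged")

#' Enumerate preprocessing pipeline specifications
#'
#' Builds the full cross-product of normalization algorithm, annotation and
#' dataset-handling factors, in deterministic order (algorithm outermost,
#' handling innermost, each in the order supplied).  Each pipeline gets a
#' stable id `"<algorithm>_<annotation>_<handling>"` used as a join key in
#' vote matrices and file names.
#'
#' @param algorithms character vector of algorithm names.
#' @param annotations character vector of annotation names.
#' @param handlings character vector of handling modes; values must be
#'   `"separate"` or `"merged"`.
#' @return A data.frame of class `pv_pipelines` with columns `id`,
#'   `algorithm`, `annotation`, `handling`; one row per pipeline.
#' @export
#' @examples
#' nrow(enumerate_pipelines())         # 24
#' nrow(enumerate_pipelines(handlings = "merged"))  # 12
enumerate_pipelines <- function(algorithms = pv_algorithms,
                                annotations = pv_annotations,
                                handlings = pv_handlings) {
  for (fac in list(algorithms = algorithms, annotations = annotations,
                   handlings = handlings)) {
    if (length(fac) == 0L) stop("each pipeline factor must be non-empty")
    if (anyDuplicated(fac)) {
      stop("duplicate entries in pipeline factor: ",
           paste(fac[duplicated(fac)], collapse = ", "))
    }
  }
  if (!all(handlings %in% pv_handlings)) {
    stop("handlings must be 'separate' or 'merged'")
  }
  grid <- expand.grid(handling = handlings, annotation = annotations,
                      algorithm = algorithms,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  specs <- data.frame(
    id = paste(grid$algorithm, grid$annotation, grid$handling, sep = "_"),
    algorithm = grid$algorithm,
    annotation = grid$annotation,
    handling = grid$handling,
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(specs$id))
  class(specs) <- c("pv_pipelines", "data.frame")
  specs
}

#' Look up pipeline specs for a set of pipeline ids
#'
#' @param ids character vector of pipeline ids.
#' @param specs a `pv_pipelines` data.frame; defaults to the full 24-way
#'   enumeration.
#' @return The matching rows of `specs`, in the order of `ids`.
#' @keywords internal
match_pipeline_specs <- function(ids, specs = enumerate_pipelines()) {
  pos <- match(ids, specs$id)
  if (anyNA(pos)) {
    stop("unknown pipeline id(s): ", paste(ids[is.na(pos)], collapse = ", "))
  }
  specs[pos, , drop = FALSE]
}

#' Run configuration
#'
#' Bundles the tunable parameters of the workflow with their defaults: the
#' survival horizon used to binarize outcome (5 years), the train/test
#' split ratio (1:1), the random-forest tuning grids, the FDR level and
#' signature-size cap for discovery, and the number of cross-validation
#' folds.
#'
#' @param seed integer master seed for all randomized stages.
#' @param horizon_years survival horizon in years; default 5.
#' @param split_ratio fraction of patients in the training half; default 0.5.
#' @param mtry_grid candidate numbers of features tried per split.
#' @param ntree_grid candidate forest sizes.
#' @param fdr_alpha adjusted-p threshold for discovery; default 0.05.
#' @param top_k_genes signature size cap for discovery; default 100.
#' @param cv_folds folds for per-signature cross-validation; default 10.
#' @param paths optional named list of input/output paths.
#' @return A list of class `pv_config`.
#' @export
run_config <- function(seed = 1L,
                       horizon_years = 5,
                       split_ratio = 0.5,
                       mtry_grid = c(1L, seq(2L, 24L, by = 2L)),
                       ntree_grid = c(500L, 1000L, 2000L, 5000L),
                       fdr_alpha = 0.05,
                       top_k_genes = 100L,
                       cv_folds = 10L,
                       paths = list()) {
  stopifnot(split_ratio > 0, split_ratio < 1,
            horizon_years > 0,
            length(mtry_grid) > 0, length(ntree_grid) > 0,
            all(mtry_grid >= 1), all(ntree_grid >= 1),
            fdr_alpha > 0, fdr_alpha <= 1,
            top_k_genes >= 1, cv_folds >= 2)
  structure(list(seed = as.integer(seed), horizon_years = horizon_years,
                 split_ratio = split_ratio,
                 mtry_grid = as.integer(mtry_grid),
                 ntree_grid = as.integer(ntree_grid),
                 fdr_alpha = fdr_alpha,
                 top_k_genes = as.integer(top_k_genes),
                 cv_folds = as.integer(cv_folds), paths = paths),
            class = "pv_config")
}
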