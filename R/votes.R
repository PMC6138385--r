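#' Engineer vote-summary features from a vote matrix
#'
#' Computes the 12 per-patient engineered counts summarizing poor-prognosis
#' votes by pipeline characteristics: the overall total; totals split by
#' dataset handling (separate / merged); one total per normalization
#' algorithm (RMA, GCRMA, MBEI, MAS5, log2 MBEI, log2 MAS5); the combined
#' RMA-and-MAS5 total (pipelines whose algorithm is RMA or MAS5, the log2
#' variants counting as their own algorithms); and totals split by
#' annotation (default / alternative).
#'
#' Partition identities hold by construction:
#' `votes_separate + votes_merged == votes_total`,
#' `votes_default_annotation + votes_alternative_annotation == votes_total`,
#' and the six per-algorithm counts sum to `votes_total`.
#'
#' @param vote_matrix patients x pipelines 0/1 matrix with pipeline-id
#'   column names.
#' @param specs optional `pv_pipelines` used to resolve column ids.
#' @return A data.frame: `patient_id` plus the 12 integer count columns.
#' @export
engineer_vote_features <- function(vote_matrix, specs = NULL) {
  if (is.null(specs)) specs <- enumerate_pipelines()
  sp <- match_pipeline_specs(colnames(vote_matrix), specs)
  count <- function(sel) {
    as.integer(rowSums(vote_matrix[, sel, drop = FALSE]))
  }
  data.frame(
    patient_id = rownames(vote_matrix),
    votes_total = count(rep(TRUE, ncol(vote_matrix))),
    votes_separate = count(sp$handling == "separate"),
    votes_merged = count(sp$handling == "merged"),
    votes_RMA = count(sp$algorithm == "RMA"),
    votes_GCRMA = count(sp$algorithm == "GCRMA"),
    votes_MBEI = count(sp$algorithm == "MBEI"),
    votes_MAS5 = count(sp$algorithm == "MAS5"),
    votes_MBEI_log2 = count(sp$algorithm == "MBEI_log2"),
    votes_MAS5_log2 = count(sp$algorithm == "MAS5_log2"),
    votes_RMA_and_MAS5 = count(sp$algorithm %in% c("RMA", "MAS5")),
    votes_default_annotation = count(sp$annotation == "default"),
    votes_alternative_annotation = count(sp$annotation == "alternative"),
    stringsAsFactors = FALSE
  )
}

#' Unanimous-vote classifier
#'
#' Assigns `poor` when every pipeline votes poor prognosis (all 1),
#' `good` when every pipeline votes good (all 0), and leaves the patient
#' `unclassified` otherwise.  Coverage is the classified fraction; with
#' many disagreeing pipelines it can be well below 1, and adding a pipeline
#' column can only break unanimity, never create it.
#'
#' @param vote_matrix patients x pipelines 0/1 matrix (>= 1 column).
#' @return A list with `labels` (factor `poor`/`good`/`unclassified`,
#'   named by patient) and `coverage` (classified fraction).
#' @export
unanimous_classify <- function(vote_matrix) {
  if (is.null(dim(vote_matrix)) || ncol(vote_matrix) < 1L) {
    stop("vote matrix must have at least one pipeline column")
  }
  tot <- rowSums(vote_matrix)
  p <- ncol(vote_matrix)
  lab <- ifelse(tot == p, "poor", ifelse(tot == 0, "good", "unclassified"))
  labels <- factor(lab, levels = c("poor", "good", "unclassified"))
  names(labels) <- rownames(vote_matrix)
  list(labels = labels,
       coverage = mean(labels != "unclassified"))
}
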