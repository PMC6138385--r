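#' Median dichotomization
#'
#' Splits a numeric vector at its median: 1 where the value is strictly
#' greater than the median, 0 otherwise.  Values exactly equal to the
#' median therefore fall in the low group, which makes the high-risk call
#' the conservative one and keeps the rule deterministic under ties.  The
#' even-length median is the mean of the two central order statistics.
#'
#' @param values numeric vector with at least two finite entries.
#' @return An integer 0/1 vector of the same length.
#' @export
#' @examples
#' median_dichotomize(c(1, 2, 3, 4))  # 0 0 1 1
median_dichotomize <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to dichotomize")
  if (any(!is.finite(values))) stop("values must all be finite")
  as.integer(values > median(values))
}

#' Score a gene signature on one abundance matrix
#'
#' Implements the two-stage median-dichotomized scoring scheme.  For each
#' signature gene, patients are dichotomized at the cohort median of that
#' gene's abundance; the per-patient score is the sum of these gene votes;
#' patients are then dichotomized again at the median score into high- and
#' low-risk groups.  With `handling = "merged"` all patients are pooled for
#' both dichotomizations; with `handling = "separate"` both are computed
#' independently within each `dataset_id` stratum, mirroring pipelines
#' that preprocess datasets independently.
#'
#' Signature genes absent from the matrix are dropped with a warning (an
#' alternative annotation may not carry every gene); if none are present
#' an error lists the missing genes.
#'
#' @param matrix genes x patients abundance matrix.
#' @param signature a `pv_signature`.
#' @param survival_table `pv_survival` table supplying `dataset_id` per
#'   patient (only needed for `handling = "separate"`).
#' @param handling `"merged"` or `"separate"`.
#' @return A data.frame with columns `patient_id`, `score`, `risk`
#'   (factor, levels `low`/`high`).
#' @export
score_signature <- function(matrix, signature, survival_table = NULL,
                            handling = c("merged", "separate")) {
  handling <- match.arg(handling)
  found <- intersect(signature$genes, rownames(matrix))
  if (length(found) == 0L) {
    stop("no signature genes found in matrix; missing: ",
         paste(signature$genes, collapse = ", "))
  }
  if (length(found) < length(signature$genes)) {
    warning(sprintf("signature '%s': %d of %d genes absent from matrix",
                    signature$name,
                    length(signature$genes) - length(found),
                    length(signature$genes)))
  }
  patients <- colnames(matrix)
  if (handling == "separate") {
    if (is.null(survival_table)) {
      stop("separate handling requires a survival table with dataset ids")
    }
    ds <- survival_table$dataset_id[match(patients,
                                          survival_table$patient_id)]
    if (anyNA(ds)) stop("patients missing from survival table")
    strata <- split(seq_along(patients), ds)
  } else {
    strata <- list(seq_along(patients))
  }
  score <- integer(length(patients))
  risk <- integer(length(patients))
  sub <- matrix[found, , drop = FALSE]
  for (idx in strata) {
    gene_votes <- t(apply(sub[, idx, drop = FALSE], 1L,
                          median_dichotomize))
    s <- as.integer(colSums(gene_votes))
    score[idx] <- s
    risk[idx] <- as.integer(s > median(s))
  }
  data.frame(patient_id = patients, score = score,
             risk = factor(ifelse(risk == 1L, "high", "low"),
                           levels = c("low", "high")),
             stringsAsFactors = FALSE)
}

#' Score a signature across all pipeline variants
#'
#' Applies [score_signature()] to every pipeline's abundance matrix and
#' assembles the binary risk calls into a patients x pipelines vote
#' matrix (1 = high risk / poor prognosis).  Each pipeline's handling mode
#' is taken from its spec (parsed from the id when `specs` is not given).
#' Patient sets are intersected across matrices; dropped patients are
#' logged, and an empty intersection is an error.
#'
#' @param matrices_by_pipeline named list of abundance matrices keyed by
#'   pipeline id.
#' @param signature a `pv_signature`.
#' @param survival_table `pv_survival` table.
#' @param specs optional `pv_pipelines`; defaults to looking ids up in the
#'   full 24-way enumeration.
#' @return Integer vote matrix, patients in rows, pipeline ids in columns
#'   (in the order of `matrices_by_pipeline`).
#' @export
score_all_pipelines <- function(matrices_by_pipeline, signature,
                                survival_table, specs = NULL) {
  ids <- names(matrices_by_pipeline)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("matrices_by_pipeline must be a named list keyed by pipeline id")
  }
  if (is.null(specs)) specs <- enumerate_pipelines()
  specs <- match_pipeline_specs(ids, specs)
  common <- Reduce(intersect, lapply(matrices_by_pipeline, colnames))
  if (length(common) == 0L) stop("no patients shared across all matrices")
  n_all <- length(unique(unlist(lapply(matrices_by_pipeline, colnames))))
  if (n_all > length(common)) {
    pv_log("warn", sprintf("restricting to %d common patients (%d dropped)",
                           length(common), n_all - length(common)))
  }
  votes <- matrix(0L, nrow = length(common), ncol = length(ids),
                  dimnames = list(common, ids))
  for (k in seq_along(ids)) {
    m <- matrices_by_pipeline[[k]][, common, drop = FALSE]
    sc <- score_signature(m, signature, survival_table,
                          handling = specs$handling[k])
    votes[, k] <- as.integer(sc$risk == "high")
  }
  votes
}
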