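#' Read a gene-abundance matrix
#'
#' Reads a tab-delimited genes x patients table.  The first column holds
#' gene ids; the header row holds patient ids.  All body cells must be
#' numeric and present; duplicate gene ids, ragged rows and missing or
#' non-numeric cells are rejected with an error naming the offending gene
#' (and patient where applicable).
#'
#' @param path file path.
#' @param pipeline_id optional pipeline id to tag the matrix with (stored
#'   as attribute `pipeline_id`).
#' @return A numeric matrix, genes in rows, patients in columns.
#' @export
read_abundance_matrix <- function(path, pipeline_id = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("abundance file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  patients <- header[-1L]
  if (length(patients) == 0L) stop("abundance file has no patient columns")
  if (anyDuplicated(patients)) {
    stop("duplicate patient ids: ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  }
  body <- fields[-1L]
  ncol_expected <- length(header)
  genes <- character(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = length(patients))
  for (i in seq_along(body)) {
    row <- body[[i]]
    gene <- row[1L]
    if (length(row) != ncol_expected) {
      stop(sprintf("ragged row for gene '%s': %d fields, expected %d",
                   gene, length(row), ncol_expected))
    }
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf(
        "non-numeric or missing value for gene '%s', patient '%s': '%s'",
        gene, patients[bad], row[-1L][bad]))
    }
    genes[i] <- gene
    mat[i, ] <- vals
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  dimnames(mat) <- list(genes, patients)
  if (!is.null(pipeline_id)) attr(mat, "pipeline_id") <- pipeline_id
  pv_log("debug", sprintf("read %d genes x %d patients from %s",
                          nrow(mat), ncol(mat), path))
  mat
}

#' Write a gene-abundance matrix
#'
#' Inverse of [read_abundance_matrix()]: tab-delimited, gene ids in the
#' first column (header `gene_id`), patient ids in the header row.
#'
#' @param mat numeric matrix with gene row names and patient column names.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Expects a tab-delimited table with columns `patient_id`, `dataset_id`,
#' `time_years`, `event` and optionally `subtype`.  Validates that times
#' are positive, events are 0/1, and patient ids are unique.
#'
#' @param path file path.
#' @return A data.frame of class `pv_survival` with one row per patient.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_survival_table(df)
}

#' Validate a clinical data.frame as a survival table
#'
#' @param df data.frame with columns `patient_id`, `dataset_id`,
#'   `time_years`, `event`, optional `subtype`.
#' @return `df` with class `pv_survival` prepended.
#' @export
as_survival_table <- function(df) {
  need <- c("patient_id", "dataset_id", "time_years", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  }
  if (!is.numeric(df$time_years) || anyNA(df$time_years) ||
      any(df$time_years <= 0)) {
    stop("time_years must be positive and non-missing")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  df$event <- as.integer(df$event)
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  if (!inherits(df, "pv_survival")) class(df) <- c("pv_survival", class(df))
  df
}

#' Write a clinical annotation table
#' @param survival_table a `pv_survival` data.frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(survival_table, path) {
  cols <- c("patient_id", "dataset_id", "time_years", "event", "subtype")
  write.table(survival_table[, intersect(cols, names(survival_table))],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene signature file
#'
#' One gene id per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @param name signature name; defaults to the file base name.
#' @return An object of class `pv_signature`: a list with `name` and
#'   `genes`.
#' @export
read_signature <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_signature(lines, name = if (is.null(name)) {
    sub("\\.[^.]*$", "", basename(path))
  } else name)
}

#' Construct a gene signature
#' @param genes character vector of gene ids (non-empty, unique).
#' @param name signature name.
#' @return An object of class `pv_signature`.
#' @export
gene_signature <- function(genes, name = "signature") {
  if (length(genes) == 0L) stop("signature has no genes")
  if (anyDuplicated(genes)) {
    stop("signature gene ids must be unique: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  structure(list(name = name, genes = as.character(genes)),
            class = "pv_signature")
}

#' Write a gene signature file
#' @param signature a `pv_signature`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  writeLines(c(paste0("# signature: ", signature$name), signature$genes),
             path)
  invisible(path)
}

#' Write an evaluation report
#'
#' Serializes an evaluation report (see [evaluate_classifier()]) to JSON
#' with provenance (seed and a digest of the configuration), plus one
#' tab-delimited Kaplan-Meier table per risk group as companion files
#' (`<path basename>_km_<group>.tsv`).  The JSON body is byte-stable for a
#' fixed report, so re-running with the same seed and configuration yields
#' identical files.
#'
#' @param report a `pv_report` list as returned by [evaluate_classifier()].
#' @param path destination path for the JSON file.
#' @param seed seed recorded as provenance.
#' @param config optional `pv_config` whose digest is recorded.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, config = NULL) {
  if (length(report) == 0L) stop("refusing to write an empty report")
  out <- report
  km <- out$km
  out$km <- NULL
  out$provenance <- list(
    seed = seed,
    config_digest = if (is.null(config)) NULL else config_digest(config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(km)) {
    stem <- sub("\\.json$", "", path)
    for (grp in names(km)) {
      write.table(km[[grp]], paste0(stem, "_km_", grp, ".tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Read back an evaluation report written by [write_report()]
#' @param path JSON path.
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Digest of a run configuration
#'
#' MD5 of the canonical JSON serialization; used as provenance in reports.
#'
#' @param config a `pv_config`.
#' @return A character scalar.
#' @export
config_digest <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a vote matrix as TSV
#' @param votes patients x pipelines binary matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_vote_matrix <- function(votes, path) {
  df <- data.frame(patient_id = rownames(votes), votes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a vote matrix written by [write_vote_matrix()]
#' @param path file path.
#' @return Patients x pipelines integer matrix.
#' @export
read_vote_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  if (!all(m %in% c(0L, 1L))) stop("vote matrix entries must be 0/1")
  m
}
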