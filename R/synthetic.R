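#' Generate a latent synthetic cohort
#'
#' Emulates the statistical structure the workflow assumes: a log2-scale
#' abundance matrix in which a subset of "signature" genes load on a single
#' per-patient latent hypoxia-activity factor `h`, while the remaining
#' background genes are independent Gaussian noise.  Patients are assigned
#' to datasets in contiguous blocks of near-equal size, and intrinsic
#' subtype labels are drawn independently of `h` (a fraction is left
#' unknown) so that subtype-stratified accuracy reporting can be exercised.
#'
#' Gene model, on the log2 scale:
#' \deqn{x_{gj} = \lambda \, h_j + \epsilon_{gj}} for signature genes and
#' \eqn{x_{gj} = \epsilon_{gj}} for background genes, with
#' \eqn{h_j \sim N(0,1)} and \eqn{\epsilon_{gj} \sim N(0,1)}.
#'
#' @param n_patients,n_genes cohort dimensions (both >= 1).
#' @param n_signature_genes number of genes loading on `h`
#'   (`<= n_genes`).
#' @param n_datasets number of datasets patients are split across.
#' @param loading_strength loading `lambda` of signature genes on `h`.
#' @param seed integer seed; the cohort is deterministic given it.
#' @param log_hr_per_unit,baseline_rate,censoring_rate passed to
#'   [generate_survival()]; defaults give roughly a 25% five-year event
#'   fraction, matching the event/censor balance typical of early
#'   breast-cancer cohorts.
#' @return A list of class `pv_cohort` with elements `abundance` (genes x
#'   patients), `hypoxia_activity` (named per-patient vector),
#'   `signature_genes`, `survival` (a `pv_survival` table), and
#'   `dataset_assignment`.
#' @export
generate_latent_cohort <- function(n_patients, n_genes, n_signature_genes,
                                   n_datasets = 1L, loading_strength = 1,
                                   seed = 1L,
                                   log_hr_per_unit = log(2),
                                   baseline_rate = 0.05,
                                   censoring_rate = 0.08) {
  stopifnot(n_patients >= 1, n_genes >= 1, n_datasets >= 1)
  if (n_signature_genes > n_genes) {
    stop("n_signature_genes must not exceed n_genes")
  }
  set.seed(derive_seed(seed, "latent_cohort"))
  patients <- sprintf("P%04d", seq_len(n_patients))
  genes <- sprintf("g%05d", seq_len(n_genes))
  h <- rnorm(n_patients)
  names(h) <- patients
  abundance <- matrix(rnorm(n_genes * n_patients), nrow = n_genes,
                      dimnames = list(genes, patients))
  sig_genes <- genes[seq_len(n_signature_genes)]
  if (n_signature_genes > 0L) {
    abundance[sig_genes, ] <- abundance[sig_genes, , drop = FALSE] +
      loading_strength * matrix(h, nrow = n_signature_genes,
                                ncol = n_patients, byrow = TRUE)
  }
  dataset <- sprintf("D%02d",
                     sort(rep_len(seq_len(n_datasets), n_patients)))
  names(dataset) <- patients
  subtype_levels <- c("LuminalA", "LuminalB", "HER2", "Basal", "NormalLike")
  subtype <- sample(c(subtype_levels, NA_character_), n_patients,
                    replace = TRUE,
                    prob = c(0.32, 0.20, 0.10, 0.15, 0.08, 0.15))
  survival <- generate_survival(h, log_hr_per_unit = log_hr_per_unit,
                                baseline_rate = baseline_rate,
                                censoring_rate = censoring_rate,
                                seed = derive_seed(seed, "survival"),
                                dataset_assignment = dataset,
                                subtype = subtype)
  structure(list(abundance = abundance, hypoxia_activity = h,
                 signature_genes = sig_genes, survival = survival,
                 dataset_assignment = dataset),
            class = "pv_cohort")
}

#' Generate survival data driven by hypoxia activity
#'
#' Event times are exponential with per-patient rate
#' `baseline_rate * exp(log_hr_per_unit * h_j)`; censoring times are
#' independent exponential with rate `censoring_rate`.  Observed time is
#' the minimum, and the event indicator is 1 when the event precedes
#' censoring.  Exponential forms keep every downstream check closed-form.
#'
#' @param hypoxia_activity named per-patient vector `h` (finite).
#' @param log_hr_per_unit log hazard ratio per unit of `h`.
#' @param baseline_rate baseline event hazard (per year, > 0).
#' @param censoring_rate censoring hazard (per year, >= 0; 0 disables
#'   censoring).
#' @param seed integer seed.
#' @param dataset_assignment optional named patient -> dataset vector.
#' @param subtype optional per-patient subtype labels.
#' @return A `pv_survival` data.frame.
#' @export
generate_survival <- function(hypoxia_activity, log_hr_per_unit = log(2),
                              baseline_rate = 0.05, censoring_rate = 0.08,
                              seed = 1L, dataset_assignment = NULL,
                              subtype = NULL) {
  if (any(!is.finite(hypoxia_activity))) {
    stop("hypoxia_activity must be finite")
  }
  stopifnot(baseline_rate > 0, censoring_rate >= 0)
  n <- length(hypoxia_activity)
  patients <- names(hypoxia_activity)
  if (is.null(patients)) patients <- sprintf("P%04d", seq_len(n))
  set.seed(seed)
  rate <- baseline_rate * exp(log_hr_per_unit * hypoxia_activity)
  t_event <- rexp(n, rate = rate)
  t_cens <- if (censoring_rate > 0) rexp(n, rate = censoring_rate) else
    rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  if (is.null(dataset_assignment)) {
    dataset_assignment <- rep("D01", n)
    names(dataset_assignment) <- patients
  }
  as_survival_table(data.frame(
    patient_id = patients,
    dataset_id = unname(dataset_assignment[patients]),
    time_years = time,
    event = event,
    subtype = if (is.null(subtype)) NA_character_ else subtype,
    stringsAsFactors = FALSE
  ))
}

#' Default per-pipeline distortion specifications
#'
#' Builds one distortion specification per pipeline: a positive affine
#' slope and intercept (drawn once, seeded), an antilog (`2^x`) monotone
#' nonlinearity for the native-scale MAS5/MBEI variants (none for the
#' log-scale algorithms), additive Gaussian noise, per-dataset batch
#' offsets applied only to separate-handling pipelines, and a gene-dropout
#' fraction applied only to alternative-annotation pipelines (emulating
#' genes lost when re-annotating probes).
#'
#' @param specs a `pv_pipelines` data.frame.
#' @param noise_sd additive noise standard deviation on the log2 scale.
#' @param batch_sd standard deviation of per (gene, dataset) batch offsets
#'   in separate-handling pipelines.
#' @param dropout_frac_alternative fraction of genes dropped in
#'   alternative-annotation pipelines (in `[0, 1)`).
#' @param seed integer seed for the slope/intercept draws.
#' @return `specs` with added columns `slope`, `intercept`, `nonlinearity`,
#'   `noise_sd`, `batch_sd`, `dropout_frac`.
#' @export
default_distortions <- function(specs, noise_sd = 0.4, batch_sd = 0.5,
                                dropout_frac_alternative = 0.05,
                                seed = 1L) {
  stopifnot(noise_sd >= 0, batch_sd >= 0,
            dropout_frac_alternative >= 0, dropout_frac_alternative < 1)
  set.seed(derive_seed(seed, "distortions"))
  n <- nrow(specs)
  out <- as.data.frame(specs)
  out$slope <- runif(n, 0.7, 1.3)
  out$intercept <- runif(n, -1, 1)
  out$nonlinearity <- ifelse(out$algorithm %in% c("MAS5", "MBEI"),
                             "antilog", "none")
  out$noise_sd <- noise_sd
  out$batch_sd <- ifelse(out$handling == "separate", batch_sd, 0)
  out$dropout_frac <- ifelse(out$annotation == "alternative",
                             dropout_frac_alternative, 0)
  out
}

#' Apply pipeline-specific distortions to a latent cohort
#'
#' Produces one abundance matrix per pipeline.  Each variant is a strictly
#' monotone transform of the latent matrix plus pipeline noise:
#' `g(slope * x + intercept + batch + noise)` where `g` is the identity or
#' `2^x`.  Batch offsets (per gene and dataset) are added only for
#' separate-handling pipelines; merged pipelines are on one common scale.
#' Dropped genes (annotation emulation) are removed from the variant.
#' With zero noise and zero dropout every variant preserves the per-gene
#' patient ranking of the latent matrix exactly.
#'
#' @param latent a `pv_cohort`.
#' @param distortion_specs data.frame from [default_distortions()] (one row
#'   per pipeline; slopes must be positive).
#' @param seed integer seed; noise, offsets and dropout are drawn from
#'   per-pipeline sub-streams so variants are independent but reproducible.
#' @return A named list of abundance matrices, one per pipeline id, each
#'   tagged with attribute `pipeline_id`.
#' @export
apply_pipeline_variants <- function(latent, distortion_specs, seed = 1L) {
  stopifnot(inherits(latent, "pv_cohort"))
  if (any(distortion_specs$slope <= 0)) {
    stop("distortion slopes must be positive (monotone transforms)")
  }
  base <- latent$abundance
  datasets <- latent$dataset_assignment[colnames(base)]
  out <- vector("list", nrow(distortion_specs))
  names(out) <- distortion_specs$id
  for (k in seq_len(nrow(distortion_specs))) {
    d <- distortion_specs[k, ]
    set.seed(derive_seed(seed, paste0("variant_", d$id)))
    m <- d$slope * base + d$intercept
    if (d$batch_sd > 0) {
      ds_levels <- unique(datasets)
      offsets <- matrix(rnorm(nrow(base) * length(ds_levels),
                              sd = d$batch_sd),
                        nrow = nrow(base),
                        dimnames = list(rownames(base), ds_levels))
      m <- m + offsets[, datasets, drop = FALSE]
    }
    if (d$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = d$noise_sd), nrow = nrow(m))
    }
    if (d$nonlinearity == "antilog") m <- 2^m
    if (d$dropout_frac > 0) {
      keep <- sort(sample(nrow(m),
                          nrow(m) - floor(d$dropout_frac * nrow(m))))
      m <- m[keep, , drop = FALSE]
    }
    attr(m, "pipeline_id") <- d$id
    out[[k]] <- m
  }
  pv_log("info", sprintf("generated %d pipeline variants (%d genes x %d patients)",
                         length(out), nrow(base), ncol(base)))
  out
}

#' Simulate a complete multi-pipeline study
#'
#' Convenience wrapper chaining [generate_latent_cohort()],
#' [default_distortions()] and [apply_pipeline_variants()], returning
#' everything downstream stages need, including a `pv_signature` made of
#' the hazard-driving latent genes (the synthetic stand-in for a published
#' hypoxia signature).
#'
#' @inheritParams generate_latent_cohort
#' @param specs pipeline enumeration; defaults to all 24.
#' @param noise_sd,batch_sd,dropout_frac_alternative passed to
#'   [default_distortions()].
#' @return A list with `latent`, `variants`, `specs`, `distortions`, and
#'   `signature`.
#' @export
simulate_cohort <- function(n_patients = 500L, n_genes = 200L,
                            n_signature_genes = 30L, n_datasets = 4L,
                            loading_strength = 1,
                            log_hr_per_unit = log(2),
                            baseline_rate = 0.05, censoring_rate = 0.08,
                            specs = enumerate_pipelines(),
                            noise_sd = 0.4, batch_sd = 0.5,
                            dropout_frac_alternative = 0,
                            seed = 1L) {
  latent <- generate_latent_cohort(
    n_patients, n_genes, n_signature_genes, n_datasets,
    loading_strength = loading_strength, seed = seed,
    log_hr_per_unit = log_hr_per_unit, baseline_rate = baseline_rate,
    censoring_rate = censoring_rate)
  distortions <- default_distortions(
    specs, noise_sd = noise_sd, batch_sd = batch_sd,
    dropout_frac_alternative = dropout_frac_alternative,
    seed = derive_seed(seed, "distortion_params"))
  variants <- apply_pipeline_variants(latent, distortions,
                                      seed = derive_seed(seed, "variants"))
  list(latent = latent, variants = variants, specs = specs,
       distortions = distortions,
       signature = gene_signature(latent$signature_genes,
                                  name = "synthetic_hypoxia"))
}
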