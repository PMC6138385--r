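# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except through the package's own writers.

fixture_survival <- function(n = 8, seed = 42, censoring_rate = 0.08) {
  h <- stats::rnorm(n)
  names(h) <- sprintf("P%04d", seq_len(n))
  generate_survival(h, seed = seed, censoring_rate = censoring_rate)
}

# tiny deterministic survival table for hand-checkable cases
fixture_tiny_survival <- function() {
  as_survival_table(data.frame(
    patient_id = c("a", "b", "c", "d"),
    dataset_id = c("D01", "D01", "D02", "D02"),
    time_years = c(2, 6.2, 3, 8),
    event = c(1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  ))
}

# random small survival dataset for oracle sweeps (n <= 8)
fixture_random_small <- function(n) {
  list(times = round(stats::rexp(n, 0.5) + 0.05, 3),
       events = stats::rbinom(n, 1, 0.7),
       x = stats::rbinom(n, 1, 0.5))
}

# random vote matrix with pipeline-id column names
fixture_vote_matrix <- function(n_patients = 40, specs = enumerate_pipelines(),
                                prob = 0.5) {
  v <- matrix(stats::rbinom(n_patients * nrow(specs), 1, prob),
              nrow = n_patients,
              dimnames = list(sprintf("P%04d", seq_len(n_patients)),
                              specs$id))
  storage.mode(v) <- "integer"
  v
}
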