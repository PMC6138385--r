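make_scan_cohort <- function(n = 300, genes = 40, drivers = 1,
                             loading = 2, seed = 71) {
  generate_latent_cohort(n, genes, drivers, loading_strength = loading,
                         seed = seed)
}

test_that("per-gene Cox scan ranks the hazard driver first", {
  lat <- generate_latent_cohort(500, 50, 1, loading_strength = 2,
                                seed = 41)
  scan <- per_gene_cox_scan(lat$abundance, lat$survival)
  expect_equal(scan$gene[1], lat$signature_genes)
  expect_equal(scan$rank, seq_len(nrow(scan)))
  expect_true(all(diff(scan$fdr_p) >= 0))
  expect_equal(scan$hr, exp(scan$beta))
})

test_that("constant genes are skipped with a warning", {
  lat <- generate_latent_cohort(100, 10, 2, seed = 6)
  m <- lat$abundance
  m["g00005", ] <- 3.14
  expect_warning(scan <- per_gene_cox_scan(m, lat$survival),
                 "constant gene")
  expect_false("g00005" %in% scan$gene)
  expect_equal(nrow(scan), 9L)

  st0 <- lat$survival
  st0$event <- 0L
  expect_error(per_gene_cox_scan(m, st0), "no events")
})

test_that("scan p-values are calibrated under the null", {
  # survival independent of all genes: raw p < 0.05 for ~5% of genes
  lat <- generate_latent_cohort(400, 1000, 0, seed = 91)
  scan <- per_gene_cox_scan(lat$abundance, lat$survival)
  expect_lt(abs(mean(scan$wald_p < 0.05) - 0.05), 0.02)
})

test_that("select_top_genes applies the FDR-then-cap rule", {
  scan <- data.frame(gene = sprintf("g%03d", 1:200),
                     beta = 0.5, hr = exp(0.5),
                     wald_p = c(seq(1e-10, 1e-4, length.out = 150),
                                seq(0.3, 0.9, length.out = 50)))
  scan$fdr_p <- bh_adjust(scan$wald_p)
  scan <- scan[order(scan$fdr_p, scan$wald_p), ]
  scan$rank <- seq_len(nrow(scan))

  n_pass <- sum(scan$fdr_p < 0.05)
  expect_gt(n_pass, 100)  # more passing than the cap
  sig <- select_top_genes(scan, top_k = 100, alpha = 0.05)
  expect_length(sig$genes, 100)
  expect_identical(sig$genes, scan$gene[1:100])

  # fewer passing than the cap: keep all with a warning
  expect_warning(sig80 <- select_top_genes(scan, top_k = n_pass + 20),
                 "keeping all")
  expect_length(sig80$genes, n_pass)

  # alpha 1 and top_k = #genes: everything in rank order
  all_sig <- select_top_genes(scan, top_k = 200, alpha = 1)
  expect_identical(all_sig$genes, scan$gene)

  scan$fdr_p <- 1
  expect_error(select_top_genes(scan), "no genes pass")
})

test_that("cross-validated classifier covers each patient exactly once", {
  lat <- make_scan_cohort(n = 200, genes = 20, drivers = 5, seed = 15)
  outcome <- make_binary_outcome(lat$survival)
  sig <- gene_signature(lat$signature_genes)
  cv <- cross_validated_signature_classifier(lat$abundance, sig, outcome,
                                             folds = 5, seed = 3,
                                             ntree = 100)
  expect_setequal(cv$patient_id, outcome$patient_id)
  expect_equal(anyDuplicated(cv$patient_id), 0L)
  expect_true(all(cv$fold %in% 1:5))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_identical(cv$predicted, as.integer(cv$probability > 0.5))
})

test_that("cross-validation is perfect on a label-copy gene and null on noise", {
  set.seed(27)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  ids <- sprintf("P%03d", 1:n)
  outcome <- data.frame(patient_id = ids, label = 1L - y, death = y)
  # one gene that exactly encodes the outcome (high abundance = death)
  m <- rbind(gcopy = ifelse(y == 1, 2, -2) + 0,
             gnoise = rnorm(n))
  colnames(m) <- ids
  for (folds in c(2L, 10L)) {
    cv <- cross_validated_signature_classifier(
      m, gene_signature("gcopy"), outcome, folds = folds, seed = 5,
      ntree = 50)
    expect_equal(mean(cv$predicted == y[match(cv$patient_id, ids)]), 1)
  }

  # pure-noise signature: out-of-fold AUC near 1/2 (n = 400)
  n2 <- 400
  y2 <- rbinom(n2, 1, 0.4)
  ids2 <- sprintf("Q%03d", 1:n2)
  m2 <- matrix(rnorm(10 * n2), 10,
               dimnames = list(paste0("ng", 1:10), ids2))
  out2 <- data.frame(patient_id = ids2, label = 1L - y2, death = y2)
  cv2 <- cross_validated_signature_classifier(
    m2, gene_signature(paste0("ng", 1:10)), out2, folds = 5, seed = 7,
    ntree = 150)
  auc <- roc_auc(cv2$probability, y2[match(cv2$patient_id, ids2)])$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)

  # class too rare for stratification
  rare <- data.frame(patient_id = ids[1:20], label = c(0L, rep(1L, 19)),
                     death = c(1L, rep(0L, 19)))
  expect_error(
    cross_validated_signature_classifier(m[, 1:20], gene_signature("gcopy"),
                                         rare, folds = 5, seed = 1),
    "too rare")
})

test_that("discovery yields one signature per merged pipeline sharing drivers", {
  sim <- simulate_cohort(n_patients = 250, n_genes = 120,
                         n_signature_genes = 40, loading_strength = 2,
                         specs = enumerate_pipelines(),
                         noise_sd = 0.3, seed = 57)
  sigs <- discover_signatures(sim$variants, sim$latent$survival,
                              top_k = 20, alpha = 0.05)
  merged_ids <- sim$specs$id[sim$specs$handling == "merged"]
  expect_setequal(names(sigs), merged_ids)
  expect_length(sigs, 12L)
  # every per-pipeline signature recovers at least one true driver gene
  drivers <- sim$latent$signature_genes
  overlap <- vapply(sigs, function(s) length(intersect(s$genes, drivers)),
                    integer(1))
  expect_true(all(overlap >= 1))
  # and the signatures share at least one gene overall
  expect_gte(length(Reduce(intersect, lapply(sigs, `[[`, "genes"))), 1)
})

test_that("meta-ensemble improves on noisy copies of the truth", {
  set.seed(64)
  n <- 1000
  y <- rbinom(n, 1, 0.4)
  ids <- sprintf("P%04d", 1:n)
  # 12 independent 80%-accurate classifications
  cls <- vapply(1:12, function(k) as.integer(xor(y, runif(n) < 0.2)),
                integer(n))
  dimnames(cls) <- list(ids, paste0("pipe", 1:12))
  outcome <- data.frame(patient_id = ids, label = 1L - y, death = y)
  part <- split_train_test(outcome, seed = 12)
  res <- meta_ensemble(cls, outcome, part, mtry_grid = c(2L, 4L),
                       ntree_grid = 200L, seed = 31)
  test_y <- y[match(part$test, ids)]
  meta_acc <- mean(res$predicted == test_y)
  single_acc <- colMeans(cls[part$test, ] == test_y)
  expect_gt(meta_acc, mean(single_acc))

  # identical perfect columns: meta accuracy 1
  perfect <- matrix(y, n, 3, dimnames = list(ids, paste0("p", 1:3)))
  res_p <- meta_ensemble(perfect, outcome, part, mtry_grid = 1L,
                         ntree_grid = 50L, seed = 2)
  expect_equal(mean(res_p$predicted == test_y), 1)

  # one perfect column among noise: meta within 0.02 of it
  noisy <- cbind(perfect[, 1, drop = FALSE],
                 vapply(1:5, function(k) rbinom(n, 1, 0.5), integer(n)))
  colnames(noisy) <- paste0("p", 1:6)
  res_n <- meta_ensemble(noisy, outcome, part, mtry_grid = c(1L, 3L),
                         ntree_grid = 200L, seed = 5)
  expect_gte(mean(res_n$predicted == test_y), 1 - 0.02)

  expect_error(meta_ensemble(perfect[, 1, drop = FALSE], outcome, part),
               "at least 2")
})

test_that("subtype accuracy is computed within labeled subgroups", {
  ids <- paste0("P", 1:8)
  outcome <- data.frame(patient_id = ids,
                        label = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                        death = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  pred <- setNames(c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L), ids)
  subtypes <- setNames(c("A", "A", "B", "B", "A", "A", "B", NA), ids)
  tab <- subtype_accuracy(pred, outcome, subtypes)
  expect_equal(tab$accuracy[tab$subtype == "A"], 1)   # A always correct
  expect_equal(tab$accuracy[tab$subtype == "B"], 0)   # B never correct
  expect_equal(tab$n[tab$subtype == "overall"], 7L)   # NA excluded
  expect_equal(tab$accuracy[tab$subtype == "overall"], 4 / 7)

  # single subtype, perfect predictions
  perfect <- setNames(outcome$death, ids)
  tab1 <- subtype_accuracy(perfect, outcome, setNames(rep("A", 8), ids))
  expect_equal(tab1$accuracy, c(1, 1))
})
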