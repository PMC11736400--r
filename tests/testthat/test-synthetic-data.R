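test_that("study-shaped cohort has the published dimensions and panel composition", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  expect_identical(dim(cohort$proteins$values), c(98L, 257L))
  expect_identical(dim(cohort$metabolites$values), c(98L, 88L))
  cls <- table(cohort$metabolites$feature_class)
  expect_identical(unname(cls[["glycerophospholipid"]]), 72L)
  expect_identical(unname(cls[["sphingolipid"]]), 14L)
  expect_identical(nrow(cohort$sheet), 98L)
  expect_identical(length(unique(cohort$sheet$subject_id)), 49L)
  expect_identical(as.vector(table(cohort$sheet$group)[c("primary", "metastatic", "control")]),
                   c(48L, 24L, 26L))
  # spiked features exist in the emitted matrices
  expect_true(all(cohort$truth$marker_effects$feature %in%
                    c(feature_ids(cohort$proteins), feature_ids(cohort$metabolites))))
})

test_that("generation is bit-identical for a fixed config and seed", {
  a <- generate_cohort(cohort_config(seed = 11, n_proteins = 50,
                                     n_metabolites = 20,
                                     n_immunoglobulin_decoys = 4))
  b <- generate_cohort(cohort_config(seed = 11, n_proteins = 50,
                                     n_metabolites = 20,
                                     n_immunoglobulin_decoys = 4))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(seed = 12, n_proteins = 50,
                                      n_metabolites = 20,
                                      n_immunoglobulin_decoys = 4))
  expect_false(identical(a$proteins$values, c2$proteins$values))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(cohort_config(n_control = -1), "n_control")
  expect_error(cohort_config(mcar_rate = 1.3), "mcar_rate")
  expect_error(cohort_config(replicate_cv = -0.1), "replicate_cv")
  expect_error(cohort_config(marker_effects = data.frame(
    feature = "NOT_A_FEATURE", contrast = "melanoma_vs_control", log2fc = 1)),
    "NOT_A_FEATURE")
  expect_error(cohort_config(marker_effects = data.frame(
    feature = "PRG4", contrast = "no_such_contrast", log2fc = 1)),
    "unknown contrast")
})

test_that("the age-coupled marker realises the target Spearman correlation", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  expect_lt(abs(cohort$truth$age_marker_rho - 0.34), 0.05 + 1e-9)
  subj <- !duplicated(cohort$sheet$subject_id)
  age <- cohort$sheet$age[subj]
  prg4 <- log2(rowMeans(cbind(
    cohort$proteins$values[cohort$sheet$observation_id[subj], "PRG4"]),
    na.rm = TRUE))
  rho <- suppressWarnings(cor(prg4, age, method = "spearman", use = "complete.obs"))
  expect_lt(abs(rho - 0.34), 0.15)  # replicate noise + dropout on top
})

test_that("inject_missing honours rates, edge cases, and the MNAR direction", {
  set.seed(2)
  x <- matrix(2^rnorm(1e5, 20, 2), 100, 1000)
  dimnames(x) <- list(paste0("o", 1:100), paste0("f", 1:1000))
  m <- omics_matrix(x)

  expect_identical(inject_missing(m, 0, 0, seed = 1), m)
  all_na <- inject_missing(m, 1, 0, seed = 1)
  expect_true(all(is.na(all_na$values)))

  mcar <- inject_missing(m, 0.2, 0, seed = 7)
  expect_lt(abs(mean(is.na(mcar$values)) - 0.2), 0.01)

  mnar <- inject_missing(m, 0.05, 1.5, seed = 7)
  masked <- is.na(mnar$values)
  expect_lt(mean(log2(x[masked])), mean(log2(x[!masked])))

  expect_error(inject_missing(m, -0.1, 0, seed = 1), "mcar_rate")
})

test_that("spike_effects multiplies the positive group and composes to identity", {
  set.seed(4)
  n <- 500
  x <- matrix(2^rnorm(2 * n, 20, 1), n, 2,
              dimnames = list(paste0("o", seq_len(n)), c("PRG4", "OTHER")))
  sheet <- sample_sheet(paste0("o", seq_len(n)), paste0("o", seq_len(n)),
                        rep(c("primary", "control"), each = n / 2), 1L)
  m <- omics_matrix(x)

  eff0 <- data.frame(feature = "PRG4", contrast = "melanoma_vs_control", log2fc = 0)
  expect_equal(spike_effects(m, sheet, eff0)$values, m$values)

  eff1 <- data.frame(feature = "PRG4", contrast = "melanoma_vs_control", log2fc = 1)
  sp <- spike_effects(m, sheet, eff1)
  pos <- sheet$observation_id[sheet$group == "primary"]
  neg <- sheet$observation_id[sheet$group == "control"]
  ratio <- mean(sp$values[pos, "PRG4"]) / mean(sp$values[neg, "PRG4"])
  expect_lt(abs(ratio - 2), 0.25)  # law of large numbers at n = 500
  expect_equal(sp$values[, "OTHER"], m$values[, "OTHER"])

  eff_inv <- data.frame(feature = "PRG4",
                        contrast = "melanoma_vs_control", log2fc = c(1, -1))
  expect_equal(spike_effects(m, sheet, eff_inv)$values, m$values)

  expect_error(spike_effects(m, sheet, data.frame(
    feature = "NOPE", contrast = "melanoma_vs_control", log2fc = 1)), "NOPE")
})

test_that("zero-effect cohorts give uniform moderated-t p-values", {
  cfg <- cohort_config(seed = 7, n_proteins = 2000, n_metabolites = 4,
                       n_immunoglobulin_decoys = 0,
                       marker_effects = default_marker_effects()[0, ],
                       mcar_rate = 0, mnar_slope = 0, age_marker_rho = NA)
  cohort <- generate_cohort(cfg)
  pp <- preprocess_omics(cohort$proteins, seed = 1)  # no missing: imputation no-op
  de <- moderated_t_test(pp$matrix, cohort$sheet, melanoma_vs_control("subject"))
  expect_lt(abs(mean(de$p_value < 0.05) - 0.05), 0.01)
})
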