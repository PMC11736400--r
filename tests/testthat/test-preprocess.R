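make_raw <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("o", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  omics_matrix(x, layer = "raw")
}

test_that("missingness filter uses a strict 40% threshold and is idempotent", {
  x <- matrix(1, 10, 3, dimnames = list(paste0("o", 1:10), c("half", "forty", "full")))
  x[1:5, "half"] <- NA   # 50% missing -> removed
  x[1:4, "forty"] <- NA  # exactly 40% -> retained
  m <- make_raw(x)
  f <- filter_missing(m)
  expect_identical(feature_ids(f), c("forty", "full"))
  expect_identical(attr(f, "removed_features"), "half")
  expect_identical(feature_ids(filter_missing(f)), feature_ids(f))
  # no missing values: identity
  complete <- make_raw(matrix(1:20 * 1.0, 4, 5))
  expect_identical(filter_missing(complete)$values, complete$values)
})

test_that("immunoglobulin removal matches prefixes case-insensitively and is idempotent", {
  x <- matrix(1, 2, 4,
              dimnames = list(c("a", "b"), c("IGHG1", "ALB", "PRG4", "Ighm")))
  m <- make_raw(x)
  r <- remove_immunoglobulins(m)
  expect_identical(feature_ids(r), c("ALB", "PRG4"))
  expect_setequal(attr(r, "removed_features"), c("IGHG1", "Ighm"))
  expect_identical(feature_ids(remove_immunoglobulins(r)), c("ALB", "PRG4"))
  expect_identical(feature_ids(remove_immunoglobulins(make_raw(
    matrix(1, 2, 2, dimnames = list(c("a", "b"), c("ALB", "APOC4")))))),
    c("ALB", "APOC4"))
})

test_that("random-forest imputation recovers a deterministic relation", {
  # y = x exactly; one missing y must be predicted from x
  n <- 30
  x <- seq_len(n) * 1.0
  v <- cbind(x = x, y = x)
  rownames(v) <- paste0("o", seq_len(n))
  v[15, "y"] <- NA
  m <- make_raw(v)
  imp <- impute_random_forest(m, n_trees = 200, seed = 3)
  expect_identical(imp$layer, "imputed")
  expect_lt(abs(imp$values[15, "y"] - 15) / 15, 0.10)
  # unchanged observed entries
  expect_identical(imp$values[-15, ], v[-15, ])
  # deterministic
  imp2 <- impute_random_forest(m, n_trees = 200, seed = 3)
  expect_identical(imp$values, imp2$values)
})

test_that("imputed entries stay within the observed range of each feature", {
  set.seed(6)
  v <- matrix(2^rnorm(300, 10, 2), 30, 10,
              dimnames = list(paste0("o", 1:30), paste0("f", 1:10)))
  v[sample(length(v), 60)] <- NA
  m <- make_raw(v)
  imp <- impute_random_forest(m, n_trees = 50, seed = 1)
  for (j in seq_len(ncol(v))) {
    obs <- v[!is.na(v[, j]), j]
    filled <- imp$values[is.na(v[, j]), j]
    expect_true(all(filled >= min(obs) - 1e-9 & filled <= max(obs) + 1e-9))
  }
})

test_that("imputation handles the no-missing case and the all-missing error", {
  complete <- make_raw(matrix(1:20 * 1.0, 4, 5))
  expect_identical(impute_random_forest(complete, seed = 1)$values,
                   complete$values)
  v <- matrix(1, 4, 2, dimnames = list(paste0("o", 1:4), c("ok", "gone")))
  v[, "gone"] <- NA
  expect_error(impute_random_forest(make_raw(v), seed = 1),
               "gone.*filter_missing")
})

test_that("normalisation centres every observation median at zero", {
  const <- omics_matrix(matrix(8, 3, 5, dimnames = list(paste0("o", 1:3),
                                                        paste0("f", 1:5))),
                        layer = "imputed")
  expect_true(all(normalize_and_log(const)$values == 0))

  set.seed(7)
  v <- matrix(2^rnorm(40, 10, 1), 4, 10,
              dimnames = list(paste0("o", 1:4), paste0("f", 1:10)))
  v2 <- v; v2[2, ] <- v2[1, ] * 2  # observation 2 = observation 1 scaled x2
  nl <- normalize_and_log(omics_matrix(v2, layer = "imputed"))
  expect_equal(nl$values[1, ], nl$values[2, ])
  expect_true(all(abs(apply(nl$values, 1, median)) < 1e-9))
  expect_identical(nl$layer, "normalised_log")

  bad <- v; bad[2, 3] <- 0
  expect_error(normalize_and_log(omics_matrix(bad, layer = "imputed")),
               "observation 'o2', feature 'f3'")
})

test_that("replicate averaging collapses to one observation per subject", {
  v <- matrix(c(4, 6, 10, 10, 3, 5), 3, 2,
              dimnames = list(c("s1_r1", "s1_r2", "s2_r1"), c("fA", "fB")))
  sheet <- sample_sheet(rownames(v), c("s1", "s1", "s2"),
                        c("primary", "primary", "control"), c(1L, 2L, 1L))
  avg <- average_replicates(omics_matrix(v), sheet)
  expect_identical(observation_ids(avg$matrix), c("s1", "s2"))
  expect_identical(unname(avg$matrix$values["s1", "fA"]), 5)   # (4+6)/2
  expect_identical(unname(avg$matrix$values["s2", "fA"]), 10)  # single replicate
  expect_identical(avg$sheet$group, c("primary", "control"))

  cohort <- generate_cohort(cohort_config(seed = 2, n_proteins = 30,
                                          n_metabolites = 10,
                                          n_immunoglobulin_decoys = 2,
                                          mcar_rate = 0, mnar_slope = 0))
  avg2 <- average_replicates(cohort$proteins, cohort$sheet)
  expect_identical(nrow(avg2$matrix$values), 49L)
})

test_that("the preprocessing chain logs feature counts per stage in order", {
  cohort <- generate_cohort(cohort_config(seed = 4, n_proteins = 60,
                                          n_metabolites = 10,
                                          n_immunoglobulin_decoys = 5))
  pp <- preprocess_omics(cohort$proteins, n_trees = 15, seed = 1)
  expect_identical(pp$log$stage,
                   c("input", "missingness_filter", "immunoglobulin_removal",
                     "normalised_log"))
  expect_true(all(diff(pp$log$n_features) <= 0))
  expect_identical(pp$matrix$layer, "normalised_log")
  expect_false(anyNA(pp$matrix$values))
})
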